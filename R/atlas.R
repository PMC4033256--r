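# Symmetric VOI atlases on a regular 3-D grid. The first array axis is the
# left-right axis; voxel x is mirrored to nx + 1 - x, so the midline is the
# central sagittal voxel plane (between the two central planes for
# even-sized axes).

#' Specify one volume of interest
#'
#' Helper constructing a VOI specification for [build_symmetric_atlas]: a
#' sphere of the given radius (in voxels) around `center`. Left VOIs must
#' be named `left_*`; their right mirror is generated automatically.
#' Bilateral VOIs are built as the union of the sphere and its mirror
#' image, so they are symmetric by construction.
#'
#' @param name VOI name.
#' @param laterality `"left"` or `"bilateral"` (right VOIs are derived).
#' @param center Voxel coordinates (x, y, z) of the sphere center.
#' @param radius Sphere radius in voxels.
#' @return A `voi_spec` list.
#' @export
voi_spec <- function(name, laterality = c("left", "bilateral"), center, radius) {
  laterality <- match.arg(laterality)
  if (laterality == "left" && !startsWith(name, "left_"))
    stop_ppipet("left VOIs must be named 'left_*'; got '", name, "'")
  structure(list(name = name, laterality = laterality,
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "voi_spec")
}

sphere_mask <- function(grid_shape, center, radius) {
  if (any(center - radius < 1) || any(center + radius > grid_shape))
    stop_ppipet("VOI sphere extends outside the grid")
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2]); z <- seq_len(grid_shape[3])
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Mirror a volume across the midline sagittal plane
#'
#' Reverses the left-right (first) array axis, mapping voxel x to
#' `nx + 1 - x`.
#'
#' @param vol 3-D array.
#' @return The mirrored array.
#' @export
mirror_volume <- function(vol) {
  stopifnot(length(dim(vol)) == 3L)
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}

#' Left- and right-hemisphere voxel masks
#'
#' The left hemisphere is `x <= floor(nx / 2)`; for an odd-sized axis the
#' central plane belongs to neither hemisphere.
#'
#' @param grid_shape Integer triple.
#' @return A list of two logical arrays, `left` and `right`.
#' @export
hemisphere_masks <- function(grid_shape) {
  nx <- grid_shape[1]
  xl <- seq_len(nx) <= nx %/% 2
  xr <- seq_len(nx) >= nx - nx %/% 2 + 1
  left <- array(rep(xl, prod(grid_shape[2:3])), dim = grid_shape)
  right <- array(rep(xr, prod(grid_shape[2:3])), dim = grid_shape)
  list(left = left, right = right)
}

#' Build a left-right symmetric VOI atlas
#'
#' Paints the given VOI specifications into an integer label volume. Every
#' `left_*` spec is mirrored into a matching `right_*` VOI whose voxel set
#' is the exact reflection across the midline plane; bilateral specs are
#' symmetrized by construction. Overlapping VOIs are an error. The atlas
#' must contain the reference VOI used for intensity normalization (the
#' olfactory bulb by default).
#'
#' @param grid_shape Integer triple (nx, ny, nz).
#' @param voi_specs List of [voi_spec] objects.
#' @param reference_voi Name of the reference VOI; must be present.
#' @param voxel_size Voxel edge lengths, mm.
#' @return A `voi_atlas`: `labels` (integer 3-D array, 0 = outside),
#'   `table` (data frame: label, name, laterality, mirror), `reference_voi`,
#'   `grid_shape`, `voxel_size`.
#' @export
build_symmetric_atlas <- function(grid_shape, voi_specs,
                                  reference_voi = "olfactory_bulb",
                                  voxel_size = c(0.38, 0.38, 0.82)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  labels <- array(0L, dim = grid_shape)
  tab <- data.frame(label = integer(), name = character(),
                    laterality = character(), mirror = character(),
                    stringsAsFactors = FALSE)
  next_label <- 0L
  paint <- function(mask, name, laterality, mirror) {
    if (any(labels[mask] != 0L))
      stop_ppipet("VOI '", name, "' overlaps an existing VOI")
    next_label <<- next_label + 1L
    labels[mask] <<- next_label
    tab[nrow(tab) + 1L, ] <<- list(next_label, name, laterality, mirror)
  }
  for (spec in voi_specs) {
    stopifnot(inherits(spec, "voi_spec"))
    mask <- sphere_mask(grid_shape, spec$center, spec$radius)
    if (spec$laterality == "bilateral") {
      paint(mask | mirror_volume(mask), spec$name, "bilateral", spec$name)
    } else {
      right_name <- sub("^left_", "right_", spec$name)
      paint(mask, spec$name, "left", right_name)
      paint(mirror_volume(mask), right_name, "right", spec$name)
    }
  }
  if (!reference_voi %in% tab$name)
    stop_ppipet("atlas lacks the reference VOI '", reference_voi, "'")
  structure(list(labels = labels, table = tab, reference_voi = reference_voi,
                 grid_shape = grid_shape, voxel_size = voxel_size),
            class = "voi_atlas")
}

#' Logical mask of one VOI
#'
#' @param atlas A `voi_atlas`.
#' @param name VOI name.
#' @return Logical 3-D array.
#' @export
atlas_mask <- function(atlas, name) {
  i <- match(name, atlas$table$name)
  if (is.na(i)) stop_ppipet("unknown VOI '", name, "'")
  atlas$labels == atlas$table$label[i]
}

#' Names of all VOIs in an atlas
#' @param atlas A `voi_atlas`.
#' @param include_reference Keep the reference VOI in the result?
#' @return Character vector.
#' @export
atlas_names <- function(atlas, include_reference = TRUE) {
  nm <- atlas$table$name
  if (!include_reference) nm <- setdiff(nm, atlas$reference_voi)
  nm
}

#' Union mask of all atlas VOIs
#' @param atlas A `voi_atlas`.
#' @return Logical 3-D array.
#' @export
atlas_union_mask <- function(atlas) atlas$labels > 0L

#' @export
print.voi_atlas <- function(x, ...) {
  cat(sprintf("<voi_atlas> %s grid, %d VOIs (reference: %s)\n",
              paste(x$grid_shape, collapse = "x"), nrow(x$table),
              x$reference_voi))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Default phantom atlas
#'
#' An atlas (32 x 32 x 16 by default) with a bilateral olfactory-bulb
#' reference VOI and six left/right VOI pairs named after auditory, startle
#' and PPI-related areas (ventral secondary auditory cortex, temporal
#' association cortex, inferior and superior colliculus, medial geniculate,
#' caudal pontine reticular nucleus) -- twelve unilateral VOIs in total,
#' mirrored exactly across the midline. VOI positions and radii scale with
#' the grid; on very small grids the VOIs shrink to single voxels.
#'
#' @param grid_shape Integer triple.
#' @return A `voi_atlas`.
#' @export
default_phantom_atlas <- function(grid_shape = c(32, 32, 16)) {
  g <- as.integer(grid_shape)
  cx <- round(g[1] / 4)
  ys <- round(g[2] * c(0.32, 0.56, 0.80))
  zs <- round(g[3] * c(0.32, 0.70))
  if (anyDuplicated(c(outer(ys, zs, paste))) || cx < 1 ||
      any(ys < 1) || any(zs < 1))
    stop_ppipet("grid too small for the default phantom atlas")
  r <- max(0, min(2.2, (min(diff(ys)) - 1) / 2, (diff(zs) - 1) / 2,
                  cx - 1, min(ys) - 1, g[2] - max(ys),
                  min(zs) - 1, g[3] - max(zs)))
  cref <- c(round(g[1] * 0.44), max(1, round(g[2] * 0.12)), round(g[3] / 2))
  dists <- apply(expand.grid(ys, zs), 1, function(p)
    sqrt(sum((cref - c(cx, p[1], p[2]))^2)))
  rr <- max(0, min(r + 0.8, cref[1] - 1, cref[2] - 1, cref[3] - 1,
                   g[3] - cref[3], min(dists) - r - 0.1))
  nms <- c("auv", "tea", "ic", "sc", "mg", "pnc")
  pos <- expand.grid(z = zs, y = ys)  # y-major to pair areas per y-band
  specs <- c(
    list(voi_spec("olfactory_bulb", "bilateral", cref, rr)),
    lapply(seq_along(nms), function(i)
      voi_spec(paste0("left_", nms[i]), "left",
               c(cx, pos$y[i], pos$z[i]), r)))
  build_symmetric_atlas(grid_shape, specs)
}
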