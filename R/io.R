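# File interfaces: TSV tables, NIfTI volumes, JSON sidecars, YAML configs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write per-trial startle measures as TSV with a JSON sidecar
#'
#' One row per trial (`trial`, `block`, `kind`, `prepulse_level`,
#' `startle_level`, `isi`, `amplitude`, `normalized_amplitude`); the
#' generating subject profile and seed, when given, go to a `.json`
#' sidecar next to the table.
#'
#' @param measures A `startle_measures` frame.
#' @param path Output TSV path.
#' @param plan Optional `session_plan` contributing `startle_level`/`isi`.
#' @param profile Optional `subject_profile` for the sidecar.
#' @param seed Optional seed for the sidecar.
#' @return `path`, invisibly.
#' @export
write_startle_tsv <- function(measures, path, plan = NULL, profile = NULL,
                              seed = NULL) {
  out <- as.data.frame(measures)
  if (!is.null(plan)) {
    out$startle_level <- plan$trials$startle_level[match(out$trial, plan$trials$trial)]
    out$isi <- plan$trials$isi[match(out$trial, plan$trials$trial)]
  }
  write_tsv(out, path)
  if (!is.null(profile) || !is.null(seed)) {
    side <- list(profile = if (is.null(profile)) NULL else unclass(profile),
                 seed = seed)
    jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read per-trial startle measures from TSV
#'
#' @param path TSV written by [write_startle_tsv].
#' @return A `startle_measures` frame.
#' @export
read_startle_tsv <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("startle_measures", class(out))
  out
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths, mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(0.38, 0.38, 0.82)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @return A plain 3-D array with a `voxel_size` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)
  out
}

#' Write a phantom cohort as one NIfTI per subject and condition
#'
#' Files are named `<subject>_<condition>.nii.gz`; the covariates and the
#' generating truth go to `cohort.json`.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in cohort$conditions)
    for (s in cohort$subjects)
      write_volume_nifti(cohort$volumes[[cond]][[s]],
                         file.path(dir, paste0(s, "_", cond, ".nii.gz")),
                         cohort$voxel_size)
  meta <- list(subjects = cohort$subjects, conditions = cohort$conditions,
               covariate = as.list(cohort$covariate),
               truth = cohort$truth, normalized = isTRUE(cohort$normalized))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort_nifti]
#'
#' @param dir Cohort directory.
#' @param atlas The `voi_atlas` of the cohort grid.
#' @return A `pet_cohort`.
#' @export
read_cohort_nifti <- function(dir, atlas) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  volumes <- lapply(stats::setNames(meta$conditions, meta$conditions), function(cond)
    lapply(stats::setNames(meta$subjects, meta$subjects), function(s)
      read_volume_nifti(file.path(dir, paste0(s, "_", cond, ".nii.gz")))))
  truth <- if (is.data.frame(meta$truth) && nrow(meta$truth))
    effect_table(meta$truth$voi, meta$truth$condition, meta$truth$effect,
                 meta$truth$covariate_beta) else effect_table()
  structure(list(subjects = meta$subjects, conditions = meta$conditions,
                 volumes = volumes,
                 covariate = unlist(meta$covariate)[meta$subjects],
                 truth = truth, grid_shape = atlas$grid_shape,
                 voxel_size = atlas$voxel_size, atlas = atlas,
                 normalized = isTRUE(meta$normalized)),
            class = "pet_cohort")
}

#' Write a VOI atlas (NIfTI labels + TSV name table)
#'
#' @param atlas A `voi_atlas`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(atlas$labels, file.path(dir, "atlas_labels.nii.gz"),
                     atlas$voxel_size)
  tab <- atlas$table
  tab$reference <- tab$name == atlas$reference_voi
  write_tsv(tab, file.path(dir, "atlas_names.tsv"))
  invisible(dir)
}

#' Read a VOI atlas written by [write_atlas]
#'
#' @param dir Atlas directory.
#' @return A `voi_atlas`.
#' @export
read_atlas <- function(dir) {
  vol <- read_volume_nifti(file.path(dir, "atlas_labels.nii.gz"))
  tab <- read_tsv(file.path(dir, "atlas_names.tsv"))
  reference <- tab$name[tab$reference][1]
  structure(list(labels = array(as.integer(round(vol)), dim = dim(vol)),
                 table = tab[, c("label", "name", "laterality", "mirror")],
                 reference_voi = reference, grid_shape = dim(vol),
                 voxel_size = as.numeric(attr(vol, "voxel_size"))[1:3]),
            class = "voi_atlas")
}

#' Write a statistic map (NIfTI values + p + JSON sidecar)
#'
#' @param map A `stat_map`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>_p.nii.gz` and `<prefix>.json`.
#' @param voxel_size Voxel edge lengths, mm.
#' @return `prefix`, invisibly.
#' @export
write_stat_map <- function(map, prefix, voxel_size = c(0.38, 0.38, 0.82)) {
  vals <- map$values; vals[!is.finite(vals)] <- 0
  p <- map$p; p[!is.finite(p)] <- 1
  write_volume_nifti(vals, paste0(prefix, ".nii.gz"), voxel_size)
  write_volume_nifti(p, paste0(prefix, "_p.nii.gz"), voxel_size)
  jsonlite::write_json(list(stat_kind = map$stat_kind, df = map$df, n = map$n,
                            comparison = map$comparison,
                            undefined_voxels = sum(!is.finite(map$values))),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a BAEP sweep series as per-level TSV tables
#'
#' Each level becomes `level_<dB>.tsv` with a `time_ms` column followed by
#' one column per sweep.
#'
#' @param series A `baep_series`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_baep_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series$levels)) {
    sw <- t(series$sweeps[[i]])
    colnames(sw) <- paste0("sweep_", seq_len(ncol(sw)))
    write_tsv(data.frame(time_ms = series$time_ms, sw),
              file.path(dir, sprintf("level_%03d.tsv", series$levels[i])))
  }
  jsonlite::write_json(list(levels = series$levels, step = series$step),
                       file.path(dir, "series.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a BAEP sweep series written by [write_baep_series]
#'
#' @param dir Series directory.
#' @return A `baep_series`.
#' @export
read_baep_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"), simplifyVector = TRUE)
  time_ms <- NULL
  sweeps <- lapply(meta$levels, function(lv) {
    tab <- read_tsv(file.path(dir, sprintf("level_%03d.tsv", lv)))
    time_ms <<- tab$time_ms
    t(as.matrix(tab[, -1, drop = FALSE]))
  })
  names(sweeps) <- as.character(meta$levels)
  structure(list(levels = meta$levels, sweeps = sweeps, time_ms = time_ms,
                 step = meta$step), class = "baep_series")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_into <- function(base, new, where = "") {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop_ppipet("unknown config key '", where, k, "'")
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_into(base[[k]], new[[k]], paste0(where, k, ".")) else new[[k]]
    }
    base
  }
  merge_into(cfg, user)
}
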