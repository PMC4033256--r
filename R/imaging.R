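# Voxelwise statistics: reference-region normalization and t/F/q/r maps.
# All tests are computed independently per voxel with no spatial smoothing.

new_stat_map <- function(kind, values, p, df, n, grid_shape, comparison = NULL) {
  structure(list(stat_kind = kind,
                 values = array(values, dim = grid_shape),
                 p = array(p, dim = grid_shape),
                 df = df, n = n, grid_shape = grid_shape,
                 comparison = comparison),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  df <- paste(x$df, collapse = ", ")
  cat(sprintf("<stat_map> %s-map (df = %s, n = %d)%s; %d/%d voxels defined\n",
              x$stat_kind, df, x$n,
              if (is.null(x$comparison)) ""
              else paste0(" ", paste(x$comparison, collapse = " vs ")),
              sum(is.finite(x$values)), length(x$values)))
  invisible(x)
}

#' Reference-region (ratio) intensity normalization
#'
#' Divides every voxel of each image by the mean of that image's reference
#' VOI (the olfactory bulb), removing per-subject global scaling; the
#' post-normalization reference-VOI mean is exactly 1, and the operation is
#' idempotent. Works on a single 3-D array or on every volume of a
#' `pet_cohort`.
#'
#' @param x A 3-D array or a `pet_cohort`.
#' @param atlas A `voi_atlas`; defaults to the cohort's own atlas.
#' @return Object of the same type, normalized.
#' @export
reference_region_normalize <- function(x, atlas = NULL) {
  if (inherits(x, "pet_cohort")) {
    atlas <- atlas %||% x$atlas
    x$volumes <- lapply(x$volumes, function(per_cond)
      lapply(per_cond, reference_region_normalize, atlas = atlas))
    x$normalized <- TRUE
    return(x)
  }
  stopifnot(inherits(atlas, "voi_atlas"), length(dim(x)) == 3L)
  ref <- atlas_mask(atlas, atlas$reference_voi)
  if (!any(ref)) stop_ppipet("reference VOI is empty")
  m <- mean(x[ref])
  if (!is.finite(m) || m <= 0)
    stop_ppipet("reference VOI mean must be positive; got ", format(m))
  x / m
}

# Vectorized paired / one-sample t on an n x V matrix of differences.
# Zero-variance voxels yield NA (undefined t).
one_sample_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- colSums(sweep(D, 2, m)^2) / (n - 1)
  se <- sqrt(s2 / n)
  t <- ifelse(se > 0, m / se, NA_real_)
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1L, n = n)
}

#' Voxelwise paired t-map between two conditions
#'
#' Per-voxel paired t-test (df = n - 1) comparing two conditions over the
#' same subjects. Positive values mean the first condition is higher.
#' Voxels with zero difference variance have an undefined t and are set to
#' `NA` (masked).
#'
#' @param cohort A `pet_cohort` holding both conditions.
#' @param a,b Condition labels; the test is `a - b`.
#' @return A `stat_map` with `stat_kind = "t"` and two-tailed p-values.
#' @export
paired_t_map <- function(cohort, a, b) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (length(cohort$subjects) < 2L) stop_ppipet("paired t needs n >= 2")
  D <- condition_matrix(cohort, a) - condition_matrix(cohort, b)
  r <- one_sample_t(D)
  new_stat_map("t", r$t, r$p, r$df, r$n, cohort$grid_shape, c(a, b))
}

#' Voxelwise repeated-measures ANOVA with Tukey post-hoc q-maps
#'
#' Per-voxel one-way repeated-measures ANOVA across k conditions (subject
#' as blocking factor; error df = (k-1)(n-1)) followed by Tukey studentized
#' range statistics for every condition pair, using the ANOVA error term:
#' `q = (mean_a - mean_b) / sqrt(MSE / n)`. q-maps are signed (positive =
#' first condition higher); their p-values come from the studentized range
#' distribution with (k, error df) and are two-sided by construction of
#' |q|.
#'
#' @param cohort A `pet_cohort`.
#' @param conditions Condition labels (default: all in the cohort); k >= 2.
#' @return A list: `f_map` (`stat_kind = "F"`, df = c(k-1, (k-1)(n-1))) and
#'   `q_maps`, a named list of pairwise `stat_map`s (`"a_vs_b"`).
#' @export
rm_anova_tukey_maps <- function(cohort, conditions = NULL) {
  stopifnot(inherits(cohort, "pet_cohort"))
  conditions <- conditions %||% cohort$conditions
  k <- length(conditions)
  if (k < 2L) stop_ppipet("repeated-measures ANOVA needs at least 2 conditions")
  n <- length(cohort$subjects)
  if (n < 3L) stop_ppipet("repeated-measures ANOVA needs n >= 3")
  Y <- lapply(conditions, function(cd) condition_matrix(cohort, cd))
  V <- ncol(Y[[1]])

  cond_means <- lapply(Y, colMeans)                      # k of length V
  grand <- Reduce(`+`, cond_means) / k
  subj_means <- Reduce(`+`, Y) / k                       # n x V
  ss_total <- Reduce(`+`, lapply(Y, function(m) colSums(sweep(m, 2, grand)^2)))
  ss_cond <- n * Reduce(`+`, lapply(cond_means, function(m) (m - grand)^2))
  ss_subj <- k * colSums(sweep(subj_means, 2, grand)^2)
  df_cond <- k - 1L
  df_err <- (k - 1L) * (n - 1L)
  ss_err <- pmax(ss_total - ss_cond - ss_subj, 0)
  # a zero error sum of squares (up to cancellation error) makes F and q
  # undefined; such voxels are masked as NA
  degenerate <- ss_err <= ss_total * 1e-12
  mse <- ss_err / df_err
  F <- ifelse(!degenerate, (ss_cond / df_cond) / mse, NA_real_)
  pF <- stats::pf(F, df_cond, df_err, lower.tail = FALSE)
  f_map <- new_stat_map("F", F, pF, c(df_cond, df_err), n,
                        cohort$grid_shape, conditions)

  se <- sqrt(mse / n)
  q_maps <- list()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    q <- ifelse(!degenerate, (cond_means[[i]] - cond_means[[j]]) / se, NA_real_)
    pq <- stats::ptukey(abs(q), nmeans = k, df = df_err, lower.tail = FALSE)
    nm <- paste0(conditions[i], "_vs_", conditions[j])
    q_maps[[nm]] <- new_stat_map("q", q, pq, c(k, df_err), n,
                                 cohort$grid_shape,
                                 c(conditions[i], conditions[j]))
  }
  list(f_map = f_map, q_maps = q_maps)
}

#' Voxelwise Pearson correlation map with a behavioral covariate
#'
#' Correlates, across subjects, each voxel of the per-subject difference
#' volumes (condition A minus B) with a scalar covariate such as the
#' relative difference of PPI and startle events. Two-tailed p-values come
#' from `t = R * sqrt((n - 2) / (1 - R^2))` with df = n - 2.
#'
#' @param diff A `cohort_diff` (see [condition_difference]) or a subjects x
#'   voxels matrix.
#' @param covariate Per-subject scalars; must not be constant. Defaults to
#'   nothing -- supply explicitly or via a `cohort_diff` produced from a
#'   cohort carrying covariates.
#' @param grid_shape Required when `diff` is a bare matrix.
#' @return A `stat_map` with `stat_kind = "r"`.
#' @export
pearson_r_map <- function(diff, covariate, grid_shape = NULL) {
  if (inherits(diff, "cohort_diff")) {
    grid_shape <- diff$grid_shape
    D <- diff$data
  } else {
    D <- diff
    if (is.null(grid_shape)) stop_ppipet("grid_shape needed for a bare matrix")
  }
  n <- nrow(D)
  if (n < 3L) stop_ppipet("correlation map needs n >= 3")
  if (length(covariate) != n) stop_ppipet("covariate length must equal n")
  if (stats::sd(covariate) == 0) stop_ppipet("covariate is constant")
  xc <- covariate - mean(covariate)
  Dc <- sweep(D, 2, colMeans(D))
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(colSums(Dc^2))
  r <- ifelse(sy > 0, as.numeric(crossprod(Dc, xc)) / (sx * sy), NA_real_)
  r <- clip(r, -1, 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  new_stat_map("r", r, p, n - 2L, n, grid_shape)
}
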