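# Empirical noise floors for voxelwise t-maps, the above-noise criterion,
# and VOI-level symmetry checks.

new_noise_floor <- function(mean_t, sd_t, criterion_t, df, n_voxels, method,
                            t_values = NULL) {
  structure(list(mean_t = mean_t, sd_t = sd_t, t_values = t_values,
                 criterion_t = criterion_t,
                 above_noise_cut = mean_t + 2 * sd_t,
                 separation_sd = if (is.null(criterion_t) || is.na(criterion_t))
                   NA_real_ else noise_floor_separation(criterion_t, mean_t, sd_t),
                 df = df, n_voxels = n_voxels, method = method),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("<noise_floor> %s: mean t = %.3f, sd = %.3f (df = %d, %d voxels)\n",
              x$method, x$mean_t, x$sd_t, x$df, x$n_voxels))
  if (is.finite(x$separation_sd))
    cat(sprintf("  criterion t = %.3f sits %.1f sd above the noise mean\n",
                x$criterion_t, x$separation_sd))
  invisible(x)
}

#' Separation of a critical value from an empirical noise floor
#'
#' `(criterion_t - mean_t) / sd_t`: how many noise standard deviations the
#' critical t-value of the main comparison lies above the mean of the null
#' t-distribution. Values of ~2 or more indicate that thresholded effects
#' rise above the measurement noise.
#'
#' @param criterion_t Critical t of the main comparison.
#' @param mean_t,sd_t Noise-floor summaries.
#' @return Separation in noise SD units.
#' @export
noise_floor_separation <- function(criterion_t, mean_t, sd_t) {
  if (sd_t <= 0) stop_ppipet("sd_t must be positive")
  (criterion_t - mean_t) / sd_t
}

#' Two-tailed critical t-value
#'
#' Convenience wrapper: `qt(1 - alpha/2, df)`. The df convention for the
#' noise-floor criterion is configurable because the split-half null test
#' (two-sample, df = n - 2) and the main paired test (df = n - 1) differ;
#' with n = 14 these give df 12 and 13.
#'
#' @param df Degrees of freedom.
#' @param alpha Two-tailed significance level.
#' @return The critical value.
#' @export
critical_t <- function(df, alpha = 0.05) stats::qt(1 - alpha / 2, df)

# Summarize a t-field over a mask, ignoring undefined (NA) voxels; the
# full field is kept on the result for inspection.
summarize_t <- function(t, mask, criterion_t, df, method) {
  v <- t[mask & is.finite(t)]
  if (!length(v)) stop_ppipet("no defined t-values inside the mask")
  new_noise_floor(mean(v), stats::sd(v), criterion_t, df, length(v), method,
                  t_values = t)
}

#' Split-half noise floor
#'
#' Randomly divides the subjects of a null condition into two equal groups,
#' computes a voxelwise two-sample t-map (pooled variance, df = n - 2)
#' between the groups, and summarizes its mean and SD over the mask. Under
#' the null this characterizes the empirical t-noise of the data; effects
#' in a real comparison are considered above noise when they exceed
#' `mean_t + 2 * sd_t`.
#'
#' @param cohort A `pet_cohort`.
#' @param condition Null condition to split (default `"background"`).
#' @param seed Optional integer seed for the random split.
#' @param mask Logical array over which to summarize; default all voxels.
#' @param criterion_t Critical t of the main comparison; default
#'   [critical_t] at `criterion_df`.
#' @param criterion_df df for the default criterion; `NULL` (default) uses
#'   the split df (n - 2).
#' @param alpha Two-tailed alpha of the criterion.
#' @return A `noise_floor`.
#' @export
split_half_noise_floor <- function(cohort, condition = "background",
                                   seed = NULL, mask = NULL,
                                   criterion_t = NULL, criterion_df = NULL,
                                   alpha = 0.05) {
  stopifnot(inherits(cohort, "pet_cohort"))
  X <- condition_matrix(cohort, condition)
  n <- nrow(X)
  if (n %% 2L != 0L)
    stop_ppipet("split-half noise floor needs an even subject count")
  local_seed(seed)
  g1 <- sort(sample.int(n, n %/% 2L))
  A <- X[g1, , drop = FALSE]
  B <- X[-g1, , drop = FALSE]
  n1 <- nrow(A); n2 <- nrow(B)
  df <- n1 + n2 - 2L
  ma <- colMeans(A); mb <- colMeans(B)
  sp2 <- (colSums(sweep(A, 2, ma)^2) + colSums(sweep(B, 2, mb)^2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (ma - mb) / se, NA_real_)
  criterion_t <- criterion_t %||% critical_t(criterion_df %||% df, alpha)
  mask <- mask %||% array(TRUE, dim = cohort$grid_shape)
  summarize_t(array(t, cohort$grid_shape), mask, criterion_t, df, "split_half")
}

#' Hemisphere-flip noise floor
#'
#' Mirrors each subject's null-condition volume across the midline sagittal
#' plane (exact reflection on a synthetic grid; no coregistration needed),
#' subtracts mirrored from original in alternating direction across
#' subjects (left-minus-right for half of them, right-minus-left for the
#' rest), and tests the differences against zero with a voxelwise paired t
#' (df = n - 1). Mean and SD of the t-values are summarized over the left
#' hemisphere only, since the field is antisymmetric by construction.
#' The alternation makes the result a pure noise estimate: an anatomical
#' asymmetry shared by all subjects cancels out of the mean difference.
#' Set `alternate = FALSE` (uniform left-minus-right) to instead test for
#' consistent lateralized differences.
#'
#' @param cohort A `pet_cohort`.
#' @param condition Null condition (default `"background"`).
#' @param mask Summary mask; default the left-hemisphere mask.
#' @param criterion_t,criterion_df,alpha As in [split_half_noise_floor];
#'   the default criterion df is n - 1.
#' @param alternate Alternate the subtraction direction across subjects?
#' @return A `noise_floor`.
#' @export
hemisphere_flip_noise_floor <- function(cohort, condition = "background",
                                        mask = NULL, criterion_t = NULL,
                                        criterion_df = NULL, alpha = 0.05,
                                        alternate = TRUE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (cohort$grid_shape[1] < 2L)
    stop_ppipet("left-right axis must hold at least 2 voxels")
  vols <- cohort$volumes[[condition]]
  if (is.null(vols)) stop_ppipet("condition '", condition, "' not in cohort")
  n <- length(vols)
  if (n < 2L) stop_ppipet("hemisphere-flip noise floor needs n >= 2")
  D <- t(vapply(seq_len(n), function(i) {
    v <- vols[[i]]
    d <- v - mirror_volume(v)
    as.numeric(if (!alternate || i %% 2L == 1L) d else -d)
  }, numeric(prod(cohort$grid_shape))))
  r <- one_sample_t(D)
  criterion_t <- criterion_t %||% critical_t(criterion_df %||% r$df, alpha)
  mask <- mask %||% hemisphere_masks(cohort$grid_shape)$left
  summarize_t(array(r$t, cohort$grid_shape), mask, criterion_t, r$df,
              "hemisphere_flip")
}

#' Threshold a statistic map into a significance mask
#'
#' Base mask: two-tailed `p < alpha`, uncorrected (no multiple-testing
#' correction -- the maps are read jointly with the noise floor instead).
#' When a noise floor is supplied, positive-signed voxels must additionally
#' reach `mean_t + 2 * sd_t` and negative-signed voxels the mirrored cut
#' `mean_t - 2 * sd_t`. Undefined (NA) voxels are excluded.
#'
#' @param map A `stat_map`.
#' @param alpha Significance level in (0, 1).
#' @param floor Optional `noise_floor`.
#' @return A logical 3-D mask array.
#' @export
threshold_and_mask <- function(map, alpha = 0.05, floor = NULL) {
  stopifnot(inherits(map, "stat_map"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_ppipet("alpha must lie in (0, 1)")
  mask <- !is.na(map$p) & map$p < alpha
  if (!is.null(floor)) {
    stopifnot(inherits(floor, "noise_floor"))
    hi <- floor$mean_t + 2 * floor$sd_t
    lo <- floor$mean_t - 2 * floor$sd_t
    above <- (map$values >= 0 & map$values >= hi) |
      (map$values < 0 & map$values <= lo)
    above[is.na(above)] <- FALSE
    mask <- mask & above
  }
  mask
}

#' VOI-level direction (symmetry) check
#'
#' For every VOI that intersects the significance mask, reports the mean of
#' the subject-mean difference volume inside the VOI and inside its
#' contralateral mirror, plus whether both means share the same sign.
#' A genuine metabolic change is expected to show a (possibly
#' subthreshold) change of the same direction contralaterally; a mean of
#' exactly zero counts as disagreement. Bilateral VOIs are compared
#' between their left and right halves.
#'
#' @param diff A `cohort_diff` or a subjects x voxels matrix.
#' @param atlas A `voi_atlas`.
#' @param mask Logical significance mask.
#' @return A data frame: `voi`, `n_mask_voxels`, `mean_voi`,
#'   `mean_contralateral`, `same_direction`.
#' @export
voi_direction_check <- function(diff, atlas, mask) {
  D <- if (inherits(diff, "cohort_diff")) diff$data else diff
  mean_vol <- array(colMeans(D), dim = atlas$grid_shape)
  if (!any(mask)) stop_ppipet("significance mask is empty")
  hemis <- hemisphere_masks(atlas$grid_shape)
  rows <- lapply(seq_len(nrow(atlas$table)), function(i) {
    name <- atlas$table$name[i]
    vm <- atlas_mask(atlas, name)
    n_hit <- sum(vm & mask)
    if (n_hit == 0L) return(NULL)
    if (atlas$table$laterality[i] == "bilateral") {
      ipsi <- vm & hemis$left
      contra <- vm & hemis$right
    } else {
      ipsi <- vm
      contra <- atlas_mask(atlas, atlas$table$mirror[i])
    }
    m_i <- mean(mean_vol[ipsi]); m_c <- mean(mean_vol[contra])
    data.frame(voi = name, n_mask_voxels = n_hit,
               mean_voi = m_i, mean_contralateral = m_c,
               same_direction = sign(m_i) == sign(m_c) & sign(m_i) != 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-VOI detections in a significance mask
#'
#' Summarizes a voxel mask at the VOI level: a VOI counts as detected when
#' more than `min_fraction` of its voxels are in the mask. Used for
#' parameter-recovery checks against the phantom ground truth.
#'
#' @param mask Logical 3-D mask.
#' @param atlas A `voi_atlas`.
#' @param min_fraction Detection threshold on the masked voxel fraction.
#' @param include_reference Include the reference VOI in the table?
#' @return A data frame: `voi`, `n_voxels`, `n_masked`, `fraction`,
#'   `detected`.
#' @export
voi_detections <- function(mask, atlas, min_fraction = 0.5,
                           include_reference = FALSE) {
  nms <- atlas_names(atlas, include_reference = include_reference)
  out <- do.call(rbind, lapply(nms, function(name) {
    vm <- atlas_mask(atlas, name)
    n <- sum(vm); hit <- sum(vm & mask)
    data.frame(voi = name, n_voxels = n, n_masked = hit,
               fraction = hit / n, detected = hit / n > min_fraction,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
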