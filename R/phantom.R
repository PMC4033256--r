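# Synthetic phantom PET cohorts with known ground truth.

PET_CONDITIONS <- c("ppi", "startle_control", "background")

#' Ground-truth effect table for phantom generation
#'
#' One row per (VOI, condition) pair: `effect` is the fractional uptake
#' change applied inside the VOI under that condition; `covariate_beta` is
#' the additional fractional change per unit of the subject covariate.
#' The reference VOI must not carry effects -- olfactory activity is
#' assumed equal across conditions, which is what makes it usable for
#' ratio normalization.
#'
#' @param voi Character vector of VOI names.
#' @param condition Condition labels (`"ppi"`, `"startle_control"`,
#'   `"background"`).
#' @param effect Fractional uptake change.
#' @param covariate_beta Fractional change per covariate unit.
#' @return An `effect_table` data frame.
#' @export
effect_table <- function(voi = character(), condition = character(),
                         effect = numeric(), covariate_beta = 0) {
  covariate_beta <- rep_len(as.numeric(covariate_beta),
                            length.out = length(voi))
  out <- data.frame(voi = as.character(voi),
                    condition = as.character(condition),
                    effect = as.numeric(effect),
                    covariate_beta = covariate_beta,
                    stringsAsFactors = FALSE)
  if (nrow(out) && !all(out$condition %in% PET_CONDITIONS))
    stop_ppipet("conditions must be one of: ",
                paste(PET_CONDITIONS, collapse = ", "))
  if (!all(is.finite(out$effect)) || !all(is.finite(out$covariate_beta)))
    stop_ppipet("effects must be finite")
  class(out) <- c("effect_table", class(out))
  out
}

#' Simulate a phantom PET cohort
#'
#' Generates per-subject, per-condition uptake volumes on the atlas grid:
#' `voxel = baseline * global_scale_s * (1 + effect + covariate_beta *
#' covariate_s) * (1 + noise)`, where `global_scale_s` is a per-subject
#' multiplicative scale (emulating dose and metabolic rate differences,
#' removed later by reference-region normalization), effects apply inside
#' their VOI under their condition, and the voxel noise is i.i.d. Gaussian
#' and multiplicative. The reference VOI may not carry effects. The
#' generating truth is stored with the cohort.
#'
#' @param atlas A `voi_atlas`.
#' @param effects An [effect_table] (or `NULL` for a pure-noise phantom).
#' @param n_subjects At least 2.
#' @param conditions Conditions to generate.
#' @param covariates Per-subject scalars (e.g. relative event difference);
#'   default all zero.
#' @param noise_sd Voxel noise SD as a fraction of the local mean.
#' @param global_scale_sd SD of the per-subject global scale around 1.
#' @param baseline Baseline uptake value, a.u.
#' @param seed Optional integer seed.
#' @param subjects Optional subject IDs.
#' @return A `pet_cohort`: `subjects`, `conditions`, `volumes`
#'   (`volumes[[condition]][[subject]]` = 3-D array), `covariate`, `truth`,
#'   `grid_shape`, `voxel_size`, `atlas`.
#' @export
simulate_pet_cohort <- function(atlas, effects = NULL, n_subjects,
                                conditions = PET_CONDITIONS,
                                covariates = NULL, noise_sd = 0.05,
                                global_scale_sd = 0.1, baseline = 100,
                                seed = NULL, subjects = NULL) {
  stopifnot(inherits(atlas, "voi_atlas"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop_ppipet("a cohort needs at least 2 subjects")
  if (is.null(effects)) effects <- effect_table()
  if (!all(effects$condition %in% PET_CONDITIONS))
    stop_ppipet("effect table references an unknown condition")
  if (!all(effects$voi %in% atlas$table$name))
    stop_ppipet("effect table references an unknown VOI")
  if (any(effects$voi == atlas$reference_voi &
            (effects$effect != 0 | effects$covariate_beta != 0)))
    stop_ppipet("the reference VOI must not carry condition effects")
  covariates <- covariates %||% rep(0, n_subjects)
  if (length(covariates) != n_subjects)
    stop_ppipet("covariates must have one value per subject")
  subjects <- subjects %||% sprintf("s%02d", seq_len(n_subjects))
  local_seed(seed)

  nv <- prod(atlas$grid_shape)
  # Per-condition effect and beta fields on the voxel grid.
  fields <- lapply(conditions, function(cond) {
    eff <- numeric(nv); beta <- numeric(nv)
    rows <- effects[effects$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      m <- atlas_mask(atlas, rows$voi[i])
      eff[m] <- eff[m] + rows$effect[i]
      beta[m] <- beta[m] + rows$covariate_beta[i]
    }
    list(effect = eff, beta = beta)
  })
  names(fields) <- conditions

  gscale <- pmax(0.2, 1 + stats::rnorm(n_subjects, 0, global_scale_sd))
  volumes <- stats::setNames(lapply(conditions, function(cond) {
    f <- fields[[cond]]
    vols <- lapply(seq_len(n_subjects), function(s) {
      mu <- baseline * gscale[s] * (1 + f$effect + f$beta * covariates[s])
      v <- if (noise_sd > 0) mu * (1 + stats::rnorm(nv, 0, noise_sd)) else mu
      array(v, dim = atlas$grid_shape)
    })
    stats::setNames(vols, subjects)
  }), conditions)

  structure(list(subjects = subjects, conditions = conditions,
                 volumes = volumes,
                 covariate = stats::setNames(covariates, subjects),
                 truth = effects, global_scale = gscale,
                 grid_shape = atlas$grid_shape,
                 voxel_size = atlas$voxel_size, atlas = atlas,
                 normalized = FALSE),
            class = "pet_cohort")
}

#' Restrict a cohort to a subset of subjects and conditions
#'
#' @param cohort A `pet_cohort`.
#' @param subjects Subject IDs (default: all).
#' @param conditions Condition labels (default: all).
#' @return A `pet_cohort`.
#' @export
subset_cohort <- function(cohort, subjects = NULL, conditions = NULL) {
  stopifnot(inherits(cohort, "pet_cohort"))
  subjects <- subjects %||% cohort$subjects
  conditions <- conditions %||% cohort$conditions
  if (!all(subjects %in% cohort$subjects)) stop_ppipet("unknown subject")
  if (!all(conditions %in% cohort$conditions)) stop_ppipet("unknown condition")
  cohort$volumes <- lapply(stats::setNames(conditions, conditions),
                           function(cd) cohort$volumes[[cd]][subjects])
  cohort$subjects <- subjects
  cohort$conditions <- conditions
  cohort$covariate <- cohort$covariate[subjects]
  cohort
}

# n x V matrix of one condition, subjects in rows.
condition_matrix <- function(cohort, condition) {
  if (!condition %in% cohort$conditions)
    stop_ppipet("condition '", condition, "' not in cohort")
  vols <- cohort$volumes[[condition]]
  nv <- prod(cohort$grid_shape)
  t(matrix(vapply(vols, as.numeric, numeric(nv)), nrow = nv,
           ncol = length(vols)))
}

#' Per-subject difference volumes between two conditions
#'
#' @param cohort A `pet_cohort`.
#' @param a,b Condition labels; the result is `a - b` per subject.
#' @return A `cohort_diff`: list with `data` (subjects x voxels matrix),
#'   `subjects`, `grid_shape`, `comparison`.
#' @export
condition_difference <- function(cohort, a, b) {
  d <- condition_matrix(cohort, a) - condition_matrix(cohort, b)
  structure(list(data = d, subjects = cohort$subjects,
                 grid_shape = cohort$grid_shape, comparison = c(a, b)),
            class = "cohort_diff")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d subjects x %s conditions on a %s grid%s\n",
              length(x$subjects), paste(x$conditions, collapse = "/"),
              paste(x$grid_shape, collapse = "x"),
              if (isTRUE(x$normalized)) " (reference-normalized)" else ""))
  invisible(x)
}

#' Default ground-truth effects for the phantom pipeline
#'
#' Injects a +12% uptake increase during the PPI condition into three of
#' the twelve default-atlas VOIs (left and right inferior colliculus, left
#' caudal pontine reticular nucleus) and couples the bilateral ventral
#' secondary auditory cortex to the behavioral covariate.
#'
#' @return An [effect_table].
#' @export
default_phantom_effects <- function() {
  effect_table(
    voi = c("left_ic", "right_ic", "left_pnc", "left_auv", "right_auv"),
    condition = c("ppi", "ppi", "ppi", "ppi", "ppi"),
    effect = c(0.12, 0.12, 0.12, 0, 0),
    covariate_beta = c(0, 0, 0, 0.002, 0.002)
  )
}
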