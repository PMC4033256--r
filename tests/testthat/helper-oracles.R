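# Independent oracles used to cross-check the vectorized implementations.
# These re-derive each statistic from first principles (explicit sums of
# squares, trial-by-trial rule application) and share no code with the
# package internals.

# Trial-by-trial event classification, written as a literal transcription
# of the rules.
oracle_classify_events <- function(measures, startle_threshold = 30,
                                   ppi_threshold = 15) {
  if (!is.null(measures$block)) measures <- measures[measures$block == "paradigm", ]
  sa_amps <- c()
  for (i in seq_len(nrow(measures)))
    if (measures$kind[i] == "startle_alone")
      sa_amps <- c(sa_amps, measures$amplitude[i])
  mean_sa <- sum(sa_amps) / length(sa_amps)
  n_ppi <- 0L; n_startle <- 0L
  for (i in seq_len(nrow(measures))) {
    kind <- measures$kind[i]; a <- measures$amplitude[i]
    if (kind == "startle_alone" && a > startle_threshold)
      n_startle <- n_startle + 1L
    if (kind == "prepulse_startle") {
      ppi <- (mean_sa - a) * 100 / mean_sa
      if (ppi > ppi_threshold) n_ppi <- n_ppi + 1L
      if (ppi < ppi_threshold) n_startle <- n_startle + 1L
    }
  }
  list(n_ppi = n_ppi, n_startle = n_startle)
}

# Closed-form paired / one-sample t for a vector of differences.
oracle_paired_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  m / (s / sqrt(n))
}

# Textbook one-way repeated-measures ANOVA decomposition for an n x k
# matrix (subjects x conditions); returns F and the Tukey q for each pair.
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cond_m <- colMeans(Y); subj_m <- rowMeans(Y)
  ss_total <- sum((Y - grand)^2)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df_err <- (k - 1) * (n - 1)
  mse <- ss_err / df_err
  F <- (ss_cond / (k - 1)) / mse
  q <- outer(cond_m, cond_m, `-`) / sqrt(mse / n)
  list(F = F, q = q, df_err = df_err, mse = mse)
}

# Textbook two-way mixed-design ANOVA (between factor: group; within
# factor: level) on a long data frame with columns subject, group, level, y.
# Equal cell sizes assumed.
oracle_mixed_anova <- function(d) {
  d$subject <- as.character(d$subject)
  subjects <- unique(d$subject)
  groups <- unique(d$group)
  levels_ <- unique(d$level)
  k <- length(levels_); g <- length(groups); N <- length(subjects)
  grand <- mean(d$y)
  subj_m <- tapply(d$y, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, unique)
  grp_m <- tapply(d$y, d$group, mean)
  lev_m <- tapply(d$y, d$level, mean)
  cell_m <- tapply(d$y, list(d$group, d$level), mean)
  n_g <- table(grp_of)

  ss_between_subj <- k * sum((subj_m - grand)^2)
  ss_group <- k * sum(n_g[groups] * (grp_m[groups] - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- N * sum((lev_m - grand)^2)
  ss_cells <- 0
  for (gr in groups) for (lv in levels_)
    ss_cells <- ss_cells + n_g[[gr]] *
      (cell_m[gr, as.character(lv)] - grp_m[[gr]] - lev_m[[as.character(lv)]] + grand)^2
  ss_total <- sum((d$y - grand)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_level - ss_cells

  df_group <- g - 1; df_subj <- N - g
  df_level <- k - 1; df_int <- (g - 1) * (k - 1); df_err <- (N - g) * (k - 1)
  list(
    F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
    F_level = (ss_level / df_level) / (ss_err_within / df_err),
    F_interaction = (ss_cells / df_int) / (ss_err_within / df_err),
    df = c(group = df_group, subj = df_subj, level = df_level,
           interaction = df_int, err = df_err)
  )
}

# Random small startle-measure tables for property tests; amplitudes are
# drawn so that exact-threshold and negative values occur.
random_measures <- function(n_trials = 30) {
  kinds <- sample(c("startle_alone", "prepulse_startle", "prepulse_alone",
                    "background"), n_trials, replace = TRUE,
                  prob = c(0.35, 0.45, 0.1, 0.1))
  if (!any(kinds == "startle_alone")) kinds[1] <- "startle_alone"
  amp <- round(rnorm(n_trials, 60, 50), 1)
  exact <- sample.int(n_trials, size = min(3, n_trials))
  amp[exact] <- 30  # lands exactly on the startle threshold for some trials
  data.frame(trial = seq_len(n_trials), block = "paradigm", kind = kinds,
             prepulse_level = ifelse(kinds %in% c("prepulse_alone", "prepulse_startle"),
                                     sample(c(68, 72, 78, 84), n_trials, TRUE), NA),
             amplitude = amp, stringsAsFactors = FALSE)
}

# Minimal cohort built directly from per-condition subject x voxel
# matrices, for toy-data oracle checks.
make_toy_cohort <- function(data, grid_shape) {
  subjects <- sprintf("s%02d", seq_len(nrow(data[[1]])))
  volumes <- lapply(data, function(m) {
    vols <- lapply(seq_len(nrow(m)), function(i) array(m[i, ], dim = grid_shape))
    stats::setNames(vols, subjects)
  })
  structure(list(subjects = subjects, conditions = names(data),
                 volumes = volumes,
                 covariate = stats::setNames(rep(0, length(subjects)), subjects),
                 truth = effect_table(), grid_shape = grid_shape,
                 voxel_size = c(1, 1, 1), atlas = NULL, normalized = FALSE),
            class = "pet_cohort")
}
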