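# Behavioral quantification: amplitude integration, PPI%, event
# classification, session-half comparisons and cohort statistics.

#' Integrate a startle trace into one amplitude
#'
#' Baseline-corrects a sampled piezo trace and integrates it over the
#' response window (default 5--105 ms after stimulus onset). The default
#' `"mean"` mode divides the integral by the window length so the result is
#' amplitude-scaled (mV) and directly comparable to mV event thresholds;
#' `"integral"` returns the raw integral in mV*ms.
#'
#' @param trace Sampled trace, mV.
#' @param time_ms Sample times, ms, relative to stimulus onset (same length
#'   as `trace`).
#' @param stim_onset_ms Stimulus onset, ms, on the `time_ms` axis.
#' @param window Response window relative to onset, ms; samples with
#'   `onset + window[1] <= t < onset + window[2]` are integrated.
#' @param baseline_window Baseline window, ms, on the `time_ms` axis
#'   (half-open, like `window`); its mean is subtracted.
#' @param mode `"mean"` (mV) or `"integral"` (mV*ms).
#' @return A single numeric amplitude.
#' @examples
#' t_ms <- seq(-50, 115, by = 0.5)
#' trace <- ifelse(t_ms >= 5 & t_ms < 105, 200, 0)
#' integrate_startle_amplitude(trace, t_ms, 0, baseline_window = c(-50, 0))
#' @export
integrate_startle_amplitude <- function(trace, time_ms, stim_onset_ms = 0,
                                        window = c(5, 105),
                                        baseline_window = c(-50, 0),
                                        mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  stopifnot(length(trace) == length(time_ms))
  w <- stim_onset_ms + window
  in_w <- time_ms >= w[1] & time_ms < w[2]
  in_b <- time_ms >= baseline_window[1] & time_ms < baseline_window[2]
  if (!any(in_b)) stop_ppipet("baseline window holds no samples")
  if (!any(in_w)) stop_ppipet("response window holds no samples")
  if (w[1] < min(time_ms) || w[2] > max(time_ms) + 1e-9)
    stop_ppipet("response window extends beyond the trace")
  m <- mean(trace[in_w] - mean(trace[in_b]))
  if (mode == "mean") m else m * diff(window)
}

#' Percent prepulse inhibition
#'
#' `PPI% = (A_startle_alone - A_prepulse_startle) * 100 / A_startle_alone`:
#' the percent reduction of the (average) startle amplitude caused by a
#' preceding prepulse. Negative values indicate facilitation.
#'
#' @param a_startle Startle-alone amplitude(s), mV; must be nonzero.
#' @param a_prepulse_startle Prepulse+startle amplitude(s), mV.
#' @return PPI in percent (vectorized).
#' @export
compute_ppi_percent <- function(a_startle, a_prepulse_startle) {
  if (any(a_startle == 0))
    stop_ppipet("PPI is undefined for a zero startle-alone amplitude")
  (a_startle - a_prepulse_startle) * 100 / a_startle
}

#' Classify startle and PPI events
#'
#' Applies the per-trial event rules to a session's paradigm block: startle
#' events are startle-alone trials with amplitude above `startle_threshold`
#' (30 mV) plus paired trials whose per-trial PPI -- computed against the
#' session-mean startle-alone amplitude -- falls below `ppi_threshold`
#' (15%); PPI events are paired trials with per-trial PPI above the
#' threshold. Trials exactly at a threshold count as neither. Habituation
#' and closing blocks are excluded.
#'
#' @param measures A `startle_measures` frame (or any data frame with
#'   `kind`, `amplitude`, and optionally `block` columns).
#' @param startle_threshold mV.
#' @param ppi_threshold Percent.
#' @return An `event_counts` list with `n_ppi` and `n_startle`.
#' @export
classify_events <- function(measures, startle_threshold = 30,
                            ppi_threshold = 15) {
  if (!is.null(measures$block)) measures <- measures[measures$block == "paradigm", ]
  sa <- measures$amplitude[measures$kind == "startle_alone"]
  if (!length(sa))
    stop_ppipet("event classification needs startle-alone trials")
  mean_sa <- mean(sa)
  if (mean_sa == 0)
    stop_ppipet("mean startle-alone amplitude is zero; per-trial PPI undefined")
  paired <- measures$amplitude[measures$kind == "prepulse_startle"]
  trial_ppi <- if (length(paired)) compute_ppi_percent(mean_sa, paired) else numeric(0)
  counts <- list(
    n_ppi = sum(trial_ppi > ppi_threshold),
    n_startle = sum(sa > startle_threshold) + sum(trial_ppi < ppi_threshold)
  )
  class(counts) <- "event_counts"
  counts
}

#' Relative difference of PPI and startle events
#'
#' `(n_PPI - n_startle) * 100 / (n_PPI + n_startle)`, in \[-100, 100\].
#' Negative values indicate more startle events, positive values more PPI
#' events; the quantity serves as the behavioral covariate for correlation
#' maps.
#'
#' @param counts An `event_counts` list, or the PPI event count.
#' @param n_startle Startle event count when `counts` is numeric.
#' @return Percent.
#' @export
relative_event_difference <- function(counts, n_startle = NULL) {
  if (inherits(counts, "event_counts")) {
    n_ppi <- counts$n_ppi; n_startle <- counts$n_startle
  } else {
    n_ppi <- counts
  }
  if (n_ppi < 0 || n_startle < 0) stop_ppipet("event counts must be nonnegative")
  if (n_ppi + n_startle == 0)
    stop_ppipet("relative difference undefined for zero events")
  (n_ppi - n_startle) * 100 / (n_ppi + n_startle)
}

#' Per-level PPI of one session
#'
#' Computes, over the paradigm block, the mean startle-alone amplitude and
#' per-prepulse-level PPI of the mean paired amplitude (percent reduction
#' relative to the mean startle-alone amplitude).
#'
#' @param measures A `startle_measures` frame.
#' @return A data frame (`prepulse_level`, `mean_paired`, `ppi_percent`)
#'   with the mean startle-alone amplitude as attribute
#'   `mean_startle_alone`.
#' @export
session_ppi <- function(measures) {
  if (!is.null(measures$block)) measures <- measures[measures$block == "paradigm", ]
  sa <- measures$amplitude[measures$kind == "startle_alone"]
  if (!length(sa)) stop_ppipet("no startle-alone trials in the paradigm block")
  mean_sa <- mean(sa)
  if (mean_sa == 0) stop_ppipet("mean startle-alone amplitude is zero")
  paired <- measures[measures$kind == "prepulse_startle", ]
  lv <- sort(unique(paired$prepulse_level))
  mp <- vapply(lv, function(l) mean(paired$amplitude[paired$prepulse_level == l]),
               numeric(1))
  out <- data.frame(prepulse_level = lv, mean_paired = mp,
                    ppi_percent = compute_ppi_percent(mean_sa, mp))
  attr(out, "mean_startle_alone") <- mean_sa
  out
}

# Early/late metric of one subject's paradigm block, split at the midpoint
# trial (by paradigm position).
half_metric <- function(measures, metric) {
  if (!is.null(measures$block)) measures <- measures[measures$block == "paradigm", ]
  n <- nrow(measures)
  halves <- list(measures[seq_len(n %/% 2), ],
                 measures[(n %/% 2 + 1):n, ])
  vapply(halves, function(h) {
    sa <- h$amplitude[h$kind == "startle_alone"]
    if (!length(sa)) return(NA_real_)
    if (metric == "startle_amplitude") return(mean(sa))
    paired <- h$amplitude[h$kind == "prepulse_startle"]
    if (!length(paired)) return(NA_real_)
    compute_ppi_percent(mean(sa), mean(paired))
  }, numeric(1))
}

#' Compare early and late session halves across subjects
#'
#' Splits every subject's paradigm block at its midpoint trial, computes an
#' early and a late mean of the chosen metric (startle-alone amplitude, or
#' overall PPI% of the half), and compares halves with a paired t-test
#' across subjects. The late-minus-early difference is reported both in
#' metric units and as percent change of the early mean, because for PPI an
#' absolute (percentage-point) and a relative reading are both meaningful.
#'
#' @param measures_list List of `startle_measures`, one per subject.
#' @param metric `"startle_amplitude"` or `"ppi_percent"`.
#' @return A `half_comparison` list: per-subject `early`/`late` values,
#'   group means, `difference` (late - early), `percent_change`, and the
#'   paired `t`, `df`, `p`.
#' @export
session_half_comparison <- function(measures_list,
                                    metric = c("startle_amplitude", "ppi_percent")) {
  metric <- match.arg(metric)
  if (length(measures_list) < 2L)
    stop_ppipet("half comparison needs at least two subjects")
  vals <- t(vapply(measures_list, half_metric, numeric(2), metric = metric))
  colnames(vals) <- c("early", "late")
  if (anyNA(vals)) stop_ppipet("a subject half lacks the trials for this metric")
  tt <- stats::t.test(vals[, "late"], vals[, "early"], paired = TRUE)
  structure(list(metric = metric,
                 early = vals[, "early"], late = vals[, "late"],
                 early_mean = mean(vals[, "early"]),
                 late_mean = mean(vals[, "late"]),
                 difference = mean(vals[, "late"] - vals[, "early"]),
                 percent_change = 100 * mean(vals[, "late"] - vals[, "early"]) /
                   mean(vals[, "early"]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "half_comparison")
}

#' @export
print.half_comparison <- function(x, ...) {
  cat(sprintf("<half_comparison> %s: early %.2f, late %.2f (diff %+.2f, %+.1f%%), t(%d) = %.3f, p = %.4g\n",
              x$metric, x$early_mean, x$late_mean, x$difference,
              x$percent_change, x$df, x$t, x$p))
  invisible(x)
}

#' Arcsine-square-root transform of percentages
#'
#' `asin(sqrt(p / 100))`, the variance-stabilizing transform applied to all
#' percentage values before parametric testing. Negative percentages
#' (startle facilitation) are transformed with their sign preserved:
#' `-asin(sqrt(|p| / 100))`. Values beyond +/-100 are clipped to the
#' transform's domain.
#'
#' @param percent Percent values.
#' @return Transformed values (radians).
#' @export
arcsin_percent <- function(percent) {
  sign(percent) * asin(sqrt(clip(abs(percent), 0, 100) / 100))
}

#' Cohort behavioral statistics
#'
#' Runs the group-level behavioral analysis: (a) arcsine-square-root
#' transform of all PPI percentages; (b) two-way mixed-design ANOVA on the
#' transformed PPI (within factor: prepulse intensity; between factor:
#' strain); (c) Sidak-adjusted simple-effect contrasts of strain at each
#' prepulse level, using the pooled mixed-ANOVA error term
#' `(MS_subjects_within + (k-1) MS_residual) / k` with Satterthwaite
#' degrees of freedom -- the standard post-hoc contrast after a mixed
#' design; (d) Mann-Whitney U tests comparing relative event difference
#' and startle amplitude between strains (exact null for small samples
#' without ties, as provided by [stats::wilcox.test]); and (e) Pearson
#' correlation between hearing threshold and relative event difference.
#'
#' @param ppi_table Long data frame: `subject`, `strain`, `prepulse_level`,
#'   `ppi_percent` -- one row per subject and level (levels balanced within
#'   subject).
#' @param subject_table One row per subject: `subject`, `strain`,
#'   `hearing_threshold`, `rel_diff`, `startle_amplitude`.
#' @return A `behavior_stats` list with elements `transformed`, `anova`
#'   (data frame: effect, df1, df2, F, p), `sidak` (per-level contrasts
#'   with raw and Sidak-adjusted p), `mann_whitney` (U and p per outcome),
#'   and `pearson` (R, p, n).
#' @export
behavioral_group_stats <- function(ppi_table, subject_table) {
  need <- c("subject", "strain", "prepulse_level", "ppi_percent")
  stopifnot(all(need %in% names(ppi_table)))
  if (length(unique(subject_table$strain)) != 2L)
    stop_ppipet("exactly two strains are required")
  counts <- table(ppi_table$subject)
  if (length(unique(counts)) != 1L)
    stop_ppipet("prepulse levels must be balanced within subjects")

  d <- data.frame(subject = factor(ppi_table$subject),
                  strain = factor(ppi_table$strain),
                  level = factor(ppi_table$prepulse_level),
                  y = arcsin_percent(ppi_table$ppi_percent))

  fit <- stats::aov(y ~ strain * level + Error(subject/level), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: subject:level"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[r],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  anova_tab <- rbind(pick(between, "strain"),
                     pick(within, "level"),
                     pick(within, "strain:level"))
  rownames(anova_tab) <- NULL

  levels_ <- levels(d$level)
  m <- length(levels_)
  # Simple-effect error term pooled from both ANOVA strata (Winer); with a
  # degenerate (zero-variance) design the contrast collapses to t = 0.
  rb <- match("Residuals", trimws(rownames(between)))
  rw <- match("Residuals", trimws(rownames(within)))
  ms_sw <- between$`Mean Sq`[rb]; df_sw <- between$Df[rb]
  ms_e <- within$`Mean Sq`[rw]; df_e <- within$Df[rw]
  ms_c <- (ms_sw + (m - 1) * ms_e) / m
  df_c <- if (ms_c > 0)
    ms_c^2 / ((ms_sw / m)^2 / df_sw + ((m - 1) * ms_e / m)^2 / df_e)
  else df_sw + df_e
  s1 <- levels(d$strain)[1]
  n1 <- length(unique(d$subject[d$strain == s1]))
  n2 <- length(unique(d$subject[d$strain != s1]))
  se_c <- sqrt(ms_c * (1 / n1 + 1 / n2))
  sidak <- do.call(rbind, lapply(levels_, function(l) {
    dl <- d[d$level == l, ]
    diff <- mean(dl$y[dl$strain == s1]) - mean(dl$y[dl$strain != s1])
    t <- if (se_c > 0) diff / se_c else if (diff == 0) 0 else sign(diff) * Inf
    p <- 2 * stats::pt(-abs(t), df_c)
    data.frame(prepulse_level = as.numeric(l), mean_diff = diff,
               t = t, df = df_c, p = p, p_sidak = 1 - (1 - p)^m)
  }))

  strains <- sort(unique(as.character(subject_table$strain)))
  g1 <- subject_table$strain == strains[1]
  mw <- function(x) {
    # ties force the tie-corrected normal approximation; that switch is
    # expected for integer-derived outcomes, so the warning is silenced
    w <- suppressWarnings(stats::wilcox.test(x[g1], x[!g1]))
    c(U = unname(w$statistic), p = w$p.value)
  }
  mann_whitney <- rbind(
    rel_diff = mw(subject_table$rel_diff),
    startle_amplitude = mw(subject_table$startle_amplitude))

  ct <- stats::cor.test(subject_table$hearing_threshold, subject_table$rel_diff)
  pearson <- list(R = unname(ct$estimate), p = ct$p.value,
                  n = nrow(subject_table))

  structure(list(transformed = d, anova = anova_tab, sidak = sidak,
                 mann_whitney = as.data.frame(mann_whitney),
                 mann_whitney_reference = strains[1],
                 pearson = pearson),
            class = "behavior_stats")
}

#' @export
print.behavior_stats <- function(x, ...) {
  cat("<behavior_stats>\nMixed ANOVA (arcsin-transformed PPI):\n")
  print(x$anova, row.names = FALSE)
  cat("Sidak per-level strain contrasts:\n")
  print(x$sidak, row.names = FALSE)
  cat("Mann-Whitney U (first group:", x$mann_whitney_reference, "):\n")
  print(x$mann_whitney)
  cat(sprintf("Pearson threshold vs relative difference: R = %.3f, p = %.4g (n = %d)\n",
              x$pearson$R, x$pearson$p, x$pearson$n))
  invisible(x)
}
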