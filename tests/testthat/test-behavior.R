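test_that("amplitude integration is baseline-corrected and window-scaled", {
  t_ms <- seq(-50, 115, by = 0.5)
  # constant trace at the baseline level integrates to zero
  expect_equal(integrate_startle_amplitude(rep(7, length(t_ms)), t_ms, 0), 0)

  # full-window rectangular pulse of 200 mV on a 12-mV baseline
  tr <- ifelse(t_ms >= 5 & t_ms < 105, 212, 12)
  expect_equal(integrate_startle_amplitude(tr, t_ms, 0), 200)

  # half-window 300-mV pulse: discrete-sum oracle over the samples
  tr2 <- ifelse(t_ms >= 5 & t_ms < 55, 300, 0)
  in_w <- t_ms >= 5 & t_ms < 105
  oracle <- sum(tr2[in_w]) / sum(in_w)
  expect_equal(integrate_startle_amplitude(tr2, t_ms, 0), oracle)
  expect_equal(oracle, 150)

  # raw-integral mode scales by the window length
  expect_equal(integrate_startle_amplitude(tr2, t_ms, 0, mode = "integral"),
               150 * 100)

  expect_error(integrate_startle_amplitude(tr2, t_ms, 50), "beyond the trace")
  expect_error(integrate_startle_amplitude(tr2, t_ms, 0,
                                           baseline_window = c(-80, -70)),
               "baseline window")
})

test_that("PPI percentage follows the percent-reduction formula", {
  expect_equal(compute_ppi_percent(100, 100), 0)
  expect_equal(compute_ppi_percent(100, 0), 100)
  expect_equal(compute_ppi_percent(200, 50), 75)
  expect_equal(compute_ppi_percent(100, 150), -50)  # facilitation
  expect_error(compute_ppi_percent(0, 10), "undefined")

  # strictly decreasing in the paired amplitude for fixed startle amplitude
  a <- seq(0, 300, by = 10)
  expect_true(all(diff(compute_ppi_percent(120, a)) < 0))
})

test_that("event classification matches hand-built counts on a 12-trial set", {
  # startle-alone {100, 140, 20, 30}: mean 72.5; two exceed 30 mV (the
  # trial at exactly 30 mV counts as neither)
  # paired vs mean 72.5: 0 -> 100%, 61.625 -> exactly 15%, 72.5 -> 0%,
  # 80 -> -10.3%, 7.25 -> 90%, 61.624 -> just over 15%, 61.626 -> just
  # under, 145 -> -100%
  measures <- data.frame(
    kind = c(rep("startle_alone", 4), rep("prepulse_startle", 8)),
    amplitude = c(100, 140, 20, 30,
                  0, 61.625, 72.5, 80, 7.25, 61.624, 61.626, 145))
  counts <- classify_events(measures)
  expect_equal(counts$n_ppi, 3)
  expect_equal(counts$n_startle, 6)
  expect_identical(oracle_classify_events(measures),
                   list(n_ppi = 3L, n_startle = 6L))
})

test_that("event classification agrees with the brute-force oracle", {
  withr::with_seed(99, {
    for (i in 1:300) {
      m <- random_measures(n_trials = sample(10:40, 1))
      got <- classify_events(m)
      want <- oracle_classify_events(m)
      expect_equal(got$n_ppi, want$n_ppi)
      expect_equal(got$n_startle, want$n_startle)
    }
  })
  expect_error(classify_events(data.frame(kind = "prepulse_startle",
                                          amplitude = 10)),
               "startle-alone")
})

test_that("relative event difference is bounded and antisymmetric", {
  expect_equal(relative_event_difference(60, 60), 0)
  expect_equal(relative_event_difference(120, 0), 100)
  expect_equal(relative_event_difference(50, 60), -100 / 11)
  expect_error(relative_event_difference(0, 0), "zero events")
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- sample(0:150, 1); b <- sample(0:150, 1)
      if (a + b == 0) next
      x <- relative_event_difference(a, b)
      expect_true(x >= -100 && x <= 100)
      expect_equal(relative_event_difference(b, a), -x)
    }
  })
})

test_that("simulated inhibition is recovered exactly as session PPI", {
  plan <- build_session_plan(seed = 6, condition = "ppi")
  profile <- subject_profile(40, noise_sd = 0, sensitization_rate = 0)
  m <- simulate_session_amplitudes(plan, profile)
  tab <- session_ppi(m)
  expect_equal(tab$ppi_percent,
               100 * inhibition_fraction(profile, tab$prepulse_level),
               tolerance = 1e-12)
})

test_that("session-half comparison matches the closed-form paired t", {
  # five subjects with fixed early/late means, via synthetic measure frames
  early <- c(10, 12, 11, 9, 14)
  late <- c(13, 14, 12, 11, 18)
  mk <- function(e, l) data.frame(
    trial = 1:4, block = "paradigm",
    kind = rep("startle_alone", 4),
    prepulse_level = NA_real_,
    amplitude = c(e, e, l, l))
  ms <- Map(mk, early, late)
  hc <- session_half_comparison(ms, metric = "startle_amplitude")
  expect_equal(hc$early, early, ignore_attr = TRUE)
  expect_equal(hc$late, late, ignore_attr = TRUE)
  expect_equal(hc$t, oracle_paired_t(late - early), tolerance = 1e-12)
  expect_equal(hc$df, 4)
  expect_equal(hc$difference, mean(late - early))

  # identical halves: zero difference, t = 0
  hc0 <- session_half_comparison(Map(mk, early, early), "startle_amplitude")
  expect_equal(hc0$difference, 0)
  expect_true(hc0$t == 0 || is.nan(hc0$t))

  expect_error(session_half_comparison(ms[1], "startle_amplitude"),
               "two subjects")
})

test_that("sensitized sessions show a late-half amplitude increase", {
  profiles <- lapply(1:4, function(i) subject_profile(25, noise_sd = 0,
                                                      sensitization_rate = 0.002))
  ms <- lapply(1:4, function(i)
    simulate_session_amplitudes(build_session_plan(seed = i, "ppi"),
                                profiles[[i]]))
  hc <- session_half_comparison(ms, "startle_amplitude")
  expect_true(all(hc$late > hc$early))
  expect_gt(hc$percent_change, 0)
})

test_that("arcsin transform is signed and clipped to the domain", {
  expect_equal(arcsin_percent(0), 0)
  expect_equal(arcsin_percent(100), pi / 2)
  expect_equal(arcsin_percent(50), asin(sqrt(0.5)))
  expect_equal(arcsin_percent(-50), -asin(sqrt(0.5)))
  expect_equal(arcsin_percent(130), pi / 2)
})

test_that("mixed ANOVA matches the textbook sums-of-squares oracle", {
  # 2 strains x 4 levels, 3 subjects per strain, deterministic toy values
  withr::with_seed(21, {
    subjects <- paste0("s", 1:6)
    strain <- rep(c("a", "b"), each = 3)
    d <- expand.grid(subject = subjects, prepulse_level = c(68, 72, 78, 84))
    d$strain <- strain[match(d$subject, subjects)]
    d$ppi_percent <- round(runif(24, 10, 90) +
                             (d$strain == "b") * 10 +
                             (d$prepulse_level - 68), 1)
  })
  subj_tab <- data.frame(subject = subjects, strain = strain,
                         hearing_threshold = c(20, 25, 22, 60, 62, 58),
                         rel_diff = c(30, 20, 25, -10, -5, 0),
                         startle_amplitude = c(250, 210, 230, 130, 110, 120))
  gs <- behavioral_group_stats(d, subj_tab)

  oracle <- oracle_mixed_anova(data.frame(
    subject = d$subject, group = d$strain, level = d$prepulse_level,
    y = arcsin_percent(d$ppi_percent)))
  a <- gs$anova
  expect_equal(a$F[a$effect == "strain"], oracle$F_group, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "level"], oracle$F_level, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "strain:level"], oracle$F_interaction,
               tolerance = 1e-10)
  expect_equal(a$df2[a$effect == "strain"], 4)
  expect_equal(a$df2[a$effect == "level"], 12)

  # Sidak adjustment of the per-level contrasts
  expect_equal(gs$sidak$p_sidak, 1 - (1 - gs$sidak$p)^4)

  # Pearson leg against cor.test
  ct <- cor.test(subj_tab$hearing_threshold, subj_tab$rel_diff)
  expect_equal(gs$pearson$R, unname(ct$estimate), tolerance = 1e-12)
})

test_that("group stats handle degenerate and separated groups", {
  # strains mirror each other subject for subject: the strain effect is
  # exactly null while subject variance is real
  d <- expand.grid(subject = paste0("s", 1:6), prepulse_level = c(68, 72, 78, 84))
  strain <- rep(c("a", "b"), each = 3)
  offsets <- c(1, 2, 3, 1, 2, 3)
  d$strain <- strain[match(d$subject, paste0("s", 1:6))]
  d$ppi_percent <- 10 + (d$prepulse_level - 68) +
    offsets[match(d$subject, paste0("s", 1:6))]
  subj_tab <- data.frame(subject = paste0("s", 1:6), strain = strain,
                         hearing_threshold = c(1, 2, 3, 4, 5, 6),
                         rel_diff = c(1, 2, 3, 4, 5, 6),
                         startle_amplitude = c(1, 2, 3, 4, 5, 6))
  gs <- behavioral_group_stats(d, subj_tab)
  expect_lt(gs$anova$F[gs$anova$effect == "strain"], 1e-10)
  expect_equal(gs$sidak$mean_diff, rep(0, 4), tolerance = 1e-12)
  expect_equal(gs$sidak$p_sidak, rep(1, 4), tolerance = 1e-6)

  # complete separation gives U = 0 for the first (alphabetical) group low
  expect_equal(unname(gs$mann_whitney["rel_diff", "U"]), 0)
})
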