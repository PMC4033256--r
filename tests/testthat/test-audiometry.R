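test_that("sweep averaging is the pointwise mean", {
  s <- sin(seq(0, 2 * pi, length.out = 50))
  expect_equal(average_sweeps(rbind(s, s, s)), s, ignore_attr = TRUE)
  expect_equal(average_sweeps(rbind(s, -s)), rep(0, 50), ignore_attr = TRUE)
  expect_error(average_sweeps(list(1:3, 1:4)), "length")

  # residual noise scales with 1/sqrt(n_sweeps)
  withr::with_seed(5, {
    sw <- matrix(rnorm(1000 * 80, sd = 2), nrow = 1000)
    expect_equal(sd(average_sweeps(sw)), 2 / sqrt(1000), tolerance = 0.2)
  })
})

test_that("response detection compares the peak to k noise SDs", {
  t_ms <- seq(0, 10, by = 0.05)
  noise <- sin(t_ms * 40) * 0.5  # deterministic 'noise' with known sd
  expect_false(detect_baep_response(rep(0, length(t_ms)), t_ms))

  wf <- noise
  wf[t_ms >= 3 & t_ms <= 4] <- 10  # deflection 10x the noise scale
  expect_true(detect_baep_response(wf, t_ms))

  # detection flips exactly at the criterion multiplier
  sd_n <- sd(wf[t_ms >= 7 & t_ms <= 10])
  peak <- max(abs(wf[t_ms >= 2 & t_ms <= 5]))
  k_star <- peak / sd_n
  expect_true(detect_baep_response(wf, t_ms, k = k_star * 0.99))
  expect_false(detect_baep_response(wf, t_ms, k = k_star * 1.01))

  expect_error(detect_baep_response(wf, t_ms, response_window = c(2, 8)),
               "disjoint")
  expect_error(detect_baep_response(wf, t_ms, response_window = c(20, 30)),
               "empty")
})

test_that("peak-to-continuous level conversion uses the 0.8509 factor", {
  expect_equal(convert_pspl_to_spl(0), 0)
  expect_equal(convert_pspl_to_spl(100), 85.09)
  expect_equal(convert_pspl_to_spl(45), 38.2905)
})

test_that("threshold is the midpoint of last response and first silence", {
  series <- simulate_baep_series(true_threshold = 50, start_level = 100,
                                 step = 10, n_sweeps = 1, noise_sd = 0)
  expect_equal(series$levels, seq(100, 40, by = -10))
  th <- estimate_hearing_threshold(series)
  expect_equal(th$lowest_eliciting, 50)
  expect_equal(th$first_silent, 40)
  expect_equal(th$value_pspl, 45)
  expect_equal(th$value_spl, 45 * 0.8509)
})

test_that("zero-noise threshold error never exceeds half a step", {
  for (t0 in c(23, 35.5, 48, 61.4, 77)) {
    series <- simulate_baep_series(t0, start_level = 100, step = 10,
                                   n_sweeps = 1, noise_sd = 0)
    est <- estimate_hearing_threshold(series)
    expect_lte(abs(est$value_pspl - t0), 5)
    # detection is monotone: every level at/above threshold responds
    expect_true(all(est$detections$response ==
                      (est$detections$level >= t0)))
  }
})

test_that("saturated and silent series are reported as errors", {
  low <- simulate_baep_series(15, start_level = 100, step = 10,
                              n_sweeps = 1, noise_sd = 0, stop_level = 20)
  expect_error(estimate_hearing_threshold(low), "below tested range")
  silent <- simulate_baep_series(120, start_level = 100, step = 10,
                                 n_sweeps = 1, noise_sd = 0, stop_level = 50)
  expect_error(estimate_hearing_threshold(silent), "above tested range")
  expect_error(simulate_baep_series(50, step = -10), "positive")
  expect_error(simulate_baep_series(50, n_sweeps = 0), "at least 1")
})

test_that("strain cohorts separate cleanly on estimated thresholds", {
  est <- function(truth_spl, seed)
    estimate_hearing_threshold(simulate_baep_series(
      truth_spl / 0.8509, n_sweeps = 200, noise_sd = 1, seed = seed))$value_spl
  withr::with_seed(31, {
    black <- vapply(1:14, function(i) est(rnorm(1, 23.6, 5.7), 100 + i), numeric(1))
    lister <- vapply(1:5, function(i) est(rnorm(1, 60.8, 2.4), 200 + i), numeric(1))
  })
  tt <- t.test(black, lister)
  expect_lt(tt$p.value, 0.001)
  expect_lt(mean(black), mean(lister))
})
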