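# BAEP simulation, sweep averaging and hearing-threshold estimation.

#' Simulate a descending-level BAEP sweep series
#'
#' Generates per-level sets of click-evoked sweep waveforms for a hearing
#' test descending from `start_level` in fixed steps. Levels at or above
#' the subject's true threshold contain a stereotyped evoked deflection (a
#' Gaussian bump at `peak_ms`) whose amplitude grows with the level excess
#' over threshold; levels below threshold contain noise only. The series
#' descends until one level below the true threshold has been tested (or to
#' `stop_level` if given).
#'
#' @param true_threshold dB pSPL.
#' @param start_level First (highest) tested level, dB pSPL.
#' @param step Level decrement, dB; must be positive.
#' @param n_sweeps Sweeps per level (1000 in a standard hearing test).
#' @param noise_sd Per-sample noise SD, a.u.
#' @param seed Optional integer seed.
#' @param stop_level Lowest level to test; default one step below the last
#'   responding level.
#' @param fs Sampling rate, Hz.
#' @param duration_ms Sweep duration, ms.
#' @param peak_ms Latency of the evoked deflection, ms.
#' @param peak_width_ms Gaussian width of the deflection, ms.
#' @param response_gain Deflection amplitude at threshold, a.u.
#' @return A `baep_series`: list with `levels` (descending dB pSPL),
#'   `sweeps` (per level, an `n_sweeps` x samples matrix), `time_ms`,
#'   `step` and the generation parameters.
#' @export
simulate_baep_series <- function(true_threshold, start_level = 100, step = 10,
                                 n_sweeps = 1000, noise_sd = 1, seed = NULL,
                                 stop_level = NULL, fs = 20000,
                                 duration_ms = 10, peak_ms = 3.5,
                                 peak_width_ms = 0.5, response_gain = 1) {
  if (step <= 0) stop_ppipet("step must be positive")
  if (n_sweeps < 1) stop_ppipet("n_sweeps must be at least 1")
  local_seed(seed)
  if (is.null(stop_level)) {
    stop_level <- start_level
    while (stop_level >= true_threshold) stop_level <- stop_level - step
  }
  levels <- seq(start_level, stop_level, by = -step)
  if (!length(levels)) stop_ppipet("no levels between start_level and stop_level")
  time_ms <- seq(0, duration_ms, by = 1000 / fs)
  shape <- exp(-0.5 * ((time_ms - peak_ms) / peak_width_ms)^2)
  sweeps <- lapply(levels, function(lv) {
    amp <- if (lv >= true_threshold)
      response_gain * (1 + (lv - true_threshold) / 10) else 0
    base <- matrix(rep(amp * shape, each = n_sweeps), nrow = n_sweeps)
    if (noise_sd > 0)
      base <- base + matrix(stats::rnorm(n_sweeps * length(time_ms), 0, noise_sd),
                            nrow = n_sweeps)
    base
  })
  names(sweeps) <- as.character(levels)
  structure(list(levels = levels, sweeps = sweeps, time_ms = time_ms,
                 step = step, true_threshold = true_threshold,
                 peak_ms = peak_ms, n_sweeps = n_sweeps),
            class = "baep_series")
}

#' Average BAEP sweeps
#'
#' Pointwise arithmetic mean of a set of equal-length sweeps, the standard
#' step that raises the evoked response out of the EEG noise (residual
#' noise falls with the square root of the sweep count).
#'
#' @param sweeps A sweeps x samples matrix, or a list of equal-length
#'   numeric vectors.
#' @return The averaged waveform.
#' @export
average_sweeps <- function(sweeps) {
  if (is.list(sweeps)) {
    len <- lengths(sweeps)
    if (length(unique(len)) != 1L) stop_ppipet("sweeps differ in length")
    sweeps <- do.call(rbind, sweeps)
  }
  stopifnot(is.matrix(sweeps), nrow(sweeps) >= 1L)
  colMeans(sweeps)
}

#' Detect an evoked response in an averaged BAEP waveform
#'
#' Declares a response present when the peak absolute amplitude inside the
#' response window exceeds `k` times the standard deviation of the
#' (disjoint) noise window. The criterion is a configurable convention; a
#' published hearing test typically reports only that levels were lowered
#' "until no further response". The default `k = 4` keeps the familywise
#' false-alarm probability over the ~60 samples of the response window
#' below about 1% for 1000-sweep averages; `k` is exposed as
#' configuration.
#'
#' @param averaged Averaged waveform.
#' @param time_ms Sample times, ms.
#' @param response_window ms interval expected to hold the evoked deflection.
#' @param noise_window ms interval holding noise only.
#' @param k Detection multiplier.
#' @return `TRUE` if a response is detected.
#' @export
detect_baep_response <- function(averaged, time_ms,
                                 response_window = c(2, 5),
                                 noise_window = c(7, 10), k = 4) {
  stopifnot(length(averaged) == length(time_ms))
  in_r <- time_ms >= response_window[1] & time_ms <= response_window[2]
  in_n <- time_ms >= noise_window[1] & time_ms <= noise_window[2]
  if (!any(in_r) || !any(in_n)) stop_ppipet("empty response or noise window")
  if (response_window[2] > noise_window[1] && response_window[1] < noise_window[2])
    stop_ppipet("response and noise windows must be disjoint")
  max(abs(averaged[in_r])) > k * stats::sd(averaged[in_n])
}

#' Convert peak to continuous sound-pressure level
#'
#' Multiplies a peak level (dB pSPL) by the calibration correction factor
#' 0.8509 to obtain the continuous level (dB SPL).
#'
#' @param value_pspl dB pSPL.
#' @param factor Correction factor.
#' @return dB SPL.
#' @export
convert_pspl_to_spl <- function(value_pspl, factor = 0.8509) {
  factor * value_pspl
}

#' Estimate the hearing threshold from a BAEP series
#'
#' Averages the sweeps of every level, scans the series from the highest
#' level downwards, and takes the threshold as the midpoint of the lowest
#' level that elicited a detectable response and the next (first silent)
#' descending level. The peak-level threshold is converted to a continuous
#' level with [convert_pspl_to_spl].
#'
#' @param series A `baep_series`.
#' @param k Detection multiplier passed to [detect_baep_response].
#' @param response_window,noise_window Windows passed to
#'   [detect_baep_response].
#' @param conversion_factor pSPL to SPL factor.
#' @return A `hearing_threshold`: `value_pspl`, `value_spl`,
#'   `lowest_eliciting`, `first_silent`, and the per-level detection table.
#' @export
estimate_hearing_threshold <- function(series, k = 4,
                                       response_window = c(2, 5),
                                       noise_window = c(7, 10),
                                       conversion_factor = 0.8509) {
  stopifnot(inherits(series, "baep_series") ||
              (is.list(series) && !is.null(series$levels) && !is.null(series$sweeps)))
  detected <- vapply(seq_along(series$levels), function(i) {
    avg <- average_sweeps(series$sweeps[[i]])
    detect_baep_response(avg, series$time_ms, response_window, noise_window, k)
  }, logical(1))
  first_silent_i <- match(FALSE, detected)
  if (is.na(first_silent_i))
    stop_ppipet("responses at every tested level; threshold below tested range",
                class = "ppipet_threshold_saturated")
  if (first_silent_i == 1L)
    stop_ppipet("no level elicited a response; threshold above tested range",
                class = "ppipet_threshold_absent")
  lowest_eliciting <- series$levels[first_silent_i - 1L]
  first_silent <- series$levels[first_silent_i]
  value_pspl <- (lowest_eliciting + first_silent) / 2
  structure(list(value_pspl = value_pspl,
                 value_spl = convert_pspl_to_spl(value_pspl, conversion_factor),
                 lowest_eliciting = lowest_eliciting,
                 first_silent = first_silent,
                 detections = data.frame(level = series$levels,
                                         response = detected)),
            class = "hearing_threshold")
}

#' @export
print.hearing_threshold <- function(x, ...) {
  cat(sprintf("<hearing_threshold> %.1f dB pSPL (= %.1f dB SPL); lowest eliciting %.0f, first silent %.0f\n",
              x$value_pspl, x$value_spl, x$lowest_eliciting, x$first_silent))
  invisible(x)
}
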