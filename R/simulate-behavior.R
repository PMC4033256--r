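# Synthetic startle-amplitude and trace generation.

# Core amplitude model shared by the fast (amplitude-level) and full
# (trace-level) simulators. Trial index is 0-based so the first trial sits
# exactly at the startle gain.
model_amplitudes <- function(plan, profile) {
  tr <- plan$trials
  n <- nrow(tr)
  if (n == 0L) return(numeric(0))
  idx <- tr$trial - 1L
  drift <- profile$startle_gain * (1 + profile$sensitization_rate * idx)
  amp <- numeric(n)
  sa <- tr$kind == "startle_alone"
  ps <- tr$kind == "prepulse_startle"
  amp[sa] <- drift[sa]
  if (any(ps)) {
    inh <- inhibition_fraction(profile, tr$prepulse_level[ps],
                               plan$background_level)
    amp[ps] <- drift[ps] * (1 - inh)
  }
  amp
}

#' Simulate per-trial startle amplitudes for one session
#'
#' Fast amplitude-level simulator: startle-alone amplitudes follow
#' `gain * (1 + sensitization_rate * trial_index)` plus Gaussian noise;
#' paired prepulse+startle amplitudes are additionally multiplied by
#' `1 - inhibition` where the inhibition fraction grows with prepulse
#' salience and hearing ability (see [inhibition_fraction]); prepulse-alone
#' and background trials yield noise-only amplitudes. With `noise_sd = 0`
#' the output is deterministic.
#'
#' @param plan A `session_plan`.
#' @param profile A `subject_profile`.
#' @param seed Optional integer seed.
#' @return A `startle_measures` data frame: `trial`, `block`, `kind`,
#'   `prepulse_level`, `amplitude` (mV) and `normalized_amplitude`
#'   (amplitude / calibration value).
#' @export
simulate_session_amplitudes <- function(plan, profile, seed = NULL) {
  stopifnot(inherits(plan, "session_plan"), inherits(profile, "subject_profile"))
  local_seed(seed)
  tr <- plan$trials
  amp <- model_amplitudes(plan, profile)
  if (nrow(tr) && profile$noise_sd > 0)
    amp <- amp + stats::rnorm(nrow(tr), 0, profile$noise_sd)
  out <- data.frame(trial = tr$trial, block = tr$block, kind = tr$kind,
                    prepulse_level = tr$prepulse_level,
                    amplitude = amp,
                    normalized_amplitude = amp / profile$calibration_value,
                    stringsAsFactors = FALSE)
  class(out) <- c("startle_measures", class(out))
  out
}

#' Simulate piezo traces for every trial of a session
#'
#' Full trace-level simulator. Each trial yields a sampled trace holding a
#' pre-stimulus baseline segment at `baseline_offset` followed by a
#' rectangular response of the trial's amplitude spanning the 5--105 ms
#' integration window after stimulus onset, so that
#' [integrate_startle_amplitude] recovers the generating amplitude exactly
#' at zero noise. Amplitude noise follows the model of
#' [simulate_session_amplitudes].
#'
#' @param plan A `session_plan`.
#' @param profile A `subject_profile`.
#' @param seed Optional integer seed.
#' @param fs Sampling rate, Hz.
#' @param baseline_ms Length of the pre-stimulus baseline segment, ms.
#' @param baseline_offset Constant baseline level added to the whole trace, mV.
#' @return A `trace_set`: list with `traces` (trials x samples matrix, mV),
#'   `time_ms` (sample times relative to stimulus onset), `window`
#'   (integration window, ms), `measures` (the generating amplitudes as a
#'   `startle_measures` frame) and the simulation parameters.
#' @export
simulate_subject_traces <- function(plan, profile, seed = NULL, fs = 2000,
                                    baseline_ms = 50, baseline_offset = 0) {
  measures <- simulate_session_amplitudes(plan, profile, seed = seed)
  window <- c(5, 105)
  time_ms <- seq(-baseline_ms, 115, by = 1000 / fs)
  in_window <- time_ms >= window[1] & time_ms < window[2]
  traces <- matrix(baseline_offset, nrow = nrow(measures), ncol = length(time_ms))
  if (nrow(measures))
    traces[, in_window] <- baseline_offset +
      matrix(measures$amplitude, nrow(measures), sum(in_window))
  structure(list(traces = traces, time_ms = time_ms, window = window,
                 baseline_window = c(-baseline_ms, 0),
                 baseline_offset = baseline_offset, fs = fs,
                 measures = measures),
            class = "trace_set")
}
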