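#' Prepulse sensitivity as a function of hearing threshold
#'
#' Maps a subject's hearing threshold (dB SPL) to its prepulse sensitivity:
#' the inhibition drive gained per dB of prepulse salience above the
#' background noise. PPI tracks the salience of the prepulse against the
#' 65-dB background rather than its absolute level, and hearing loss
#' flattens the perceived salience growth. The mapping is a logistic decay
#' from `floor + range` (normal hearing) towards `floor` (impaired hearing),
#' centred at `midpoint` dB SPL with shallow slope so that within-strain
#' threshold scatter translates into little sensitivity scatter.
#'
#' @param threshold Hearing threshold(s), dB SPL.
#' @param floor Sensitivity retained by strongly hearing-impaired subjects
#'   (per dB above background).
#' @param range Additional sensitivity of normal-hearing subjects.
#' @param midpoint Threshold (dB SPL) at which half of `range` is lost.
#' @param scale Logistic scale, dB.
#' @return Sensitivity values (dimensionless, per dB above background).
#' @export
ppi_sensitivity <- function(threshold, floor = 0.055, range = 0.065,
                            midpoint = 45, scale = 6) {
  floor + range * stats::plogis((midpoint - threshold) / scale)
}

#' Construct a subject profile for startle-session simulation
#'
#' A subject profile bundles the ground-truth parameters that drive the
#' synthetic startle model: hearing threshold, startle gain (mean
#' startle-alone amplitude at session start, mV), prepulse sensitivity
#' (`ppi_slope`, inhibition drive per dB of prepulse salience above the
#' background; defaults to [ppi_sensitivity] of the threshold), the maximal
#' attainable inhibition fraction, a within-session sensitization rate
#' (fractional amplitude growth per trial), trial-to-trial amplitude noise,
#' and the daily calibration value used to normalize amplitudes.
#'
#' @param hearing_threshold dB SPL.
#' @param startle_gain mV; must be positive.
#' @param ppi_slope Inhibition drive per dB above background.
#' @param ppi_max Maximal inhibition fraction, in \[0, 1\].
#' @param sensitization_rate Fractional amplitude drift per trial.
#' @param noise_sd Amplitude noise SD, mV (0 allowed).
#' @param calibration_value Daily calibration amplitude, mV.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(hearing_threshold,
                            startle_gain = 226,
                            ppi_slope = ppi_sensitivity(hearing_threshold),
                            ppi_max = 0.85,
                            sensitization_rate = 0.002,
                            noise_sd = 20,
                            calibration_value = 100) {
  stopifnot(is.numeric(hearing_threshold), length(hearing_threshold) == 1L)
  if (startle_gain <= 0) stop_ppipet("startle_gain must be positive")
  if (noise_sd < 0) stop_ppipet("noise_sd must be nonnegative")
  if (ppi_max < 0 || ppi_max > 1) stop_ppipet("ppi_max must lie in [0, 1]")
  structure(list(hearing_threshold = hearing_threshold,
                 startle_gain = startle_gain,
                 ppi_slope = ppi_slope,
                 ppi_max = ppi_max,
                 sensitization_rate = sensitization_rate,
                 noise_sd = noise_sd,
                 calibration_value = calibration_value),
            class = "subject_profile")
}

#' Draw a subject profile typical of one rat strain
#'
#' Samples hearing threshold and startle gain from strain-level
#' distributions: well-hearing inbred Black hooded rats (threshold
#' 23.6 +/- 5.7 dB SPL, startle gain 226 +/- 99.3 mV) or hearing-impaired
#' outbred Lister hooded rats (threshold 60.8 +/- 2.4 dB SPL, gain
#' 120.8 +/- 59.1 mV). The gain prior anchors the startle-alone amplitude
#' at session start; session means measured under sensitization drift sit
#' ~35% above it, with the strain ratio preserved. Gains are truncated
#' below at 30 mV so every subject produces classifiable startle
#' responses.
#'
#' @param strain `"black_hooded"` or `"lister_hooded"`.
#' @param seed Optional integer seed.
#' @param ... Overrides passed on to [subject_profile].
#' @return A `subject_profile`.
#' @export
strain_profile <- function(strain = c("black_hooded", "lister_hooded"),
                           seed = NULL, ...) {
  strain <- match.arg(strain)
  local_seed(seed)
  par <- switch(strain,
    black_hooded  = list(thr = c(23.6, 5.7), gain = c(226.0, 99.3)),
    lister_hooded = list(thr = c(60.8, 2.4), gain = c(120.8, 59.1)))
  thr <- stats::rnorm(1, par$thr[1], par$thr[2])
  gain <- max(30, stats::rnorm(1, par$gain[1], par$gain[2]))
  profile <- subject_profile(hearing_threshold = thr, startle_gain = gain, ...)
  profile$strain <- strain
  profile
}

#' Inhibition fraction elicited by a prepulse
#'
#' Ground-truth fractional reduction of the startle amplitude produced by a
#' prepulse of the given level: `ppi_max * min(1, ppi_slope * (level -
#' background))`, clipped to \[0, 1\]. Prepulses at or below the background
#' level elicit no inhibition; inhibition grows with prepulse salience and
#' with hearing ability (through `ppi_slope`), and saturates at `ppi_max`.
#'
#' @param profile A `subject_profile`.
#' @param prepulse_level dB SPL (vectorized).
#' @param background_level dB SPL.
#' @return Inhibition fraction(s) in \[0, 1\].
#' @export
inhibition_fraction <- function(profile, prepulse_level, background_level = 65) {
  drive <- profile$ppi_slope * pmax(0, prepulse_level - background_level)
  clip(profile$ppi_max * pmin(1, drive), 0, 1)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(paste0("<subject_profile>%s threshold=%.1f dB SPL, ",
                     "gain=%.1f mV, slope=%.4f/dB, max inh=%.2f\n"),
              if (is.null(x$strain)) "" else paste0(" ", x$strain),
              x$hearing_threshold, x$startle_gain, x$ppi_slope, x$ppi_max))
  invisible(x)
}
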