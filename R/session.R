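#' Prepulse levels used in the standard PPI paradigm
#'
#' The four prepulse sound-pressure levels (dB SPL) of the default paradigm.
#' @export
PPI_PREPULSE_LEVELS <- c(68, 72, 78, 84)

#' Build a startle-session trial plan
#'
#' Constructs the ordered trial list of one 45-min startle session. A `ppi`
#' session consists of a habituation block of 25 startle-alone trials, a
#' paradigm block of 300 trials presented in pseudorandomized (seeded
#' uniformly shuffled) order -- 30 background, 30 startle-alone, 120
#' prepulse-alone and 120 prepulse+startle trials (30 per prepulse level) --
#' and a closing block of 20 startle-alone trials. A `startle_control`
#' session replaces every paired prepulse+startle trial with a startle-alone
#' or background trial so that the paradigm block contains exactly
#' `n_startle_override` startle-alone trials (matched to the animal's
#' startle-reaction count in its PPI session, typically 65--127). A
#' `background` session exposes the animal to continuous background noise
#' only and contains no trials.
#'
#' @param seed Integer seed controlling trial order and inter-trial
#'   intervals; `NULL` draws from the active RNG stream.
#' @param condition One of `"ppi"`, `"startle_control"`, `"background"`.
#' @param n_startle_override Required for `startle_control`: the total number
#'   of startle-alone trials in the paradigm block. Must lie in \[30, 150\]
#'   so the count is reachable from the PPI composition.
#' @param background_level Continuous background level, dB SPL.
#' @param startle_level Startle pulse level, dB SPL.
#' @param prepulse_levels Prepulse levels, dB SPL (30 trials each per kind).
#' @param isi_range Inter-trial interval range in seconds, drawn uniformly.
#' @param prepulse_gap_ms Prepulse to startle-pulse onset gap in paired
#'   trials, milliseconds.
#' @return A `session_plan`: list with `trials` (data frame: `trial`,
#'   `block`, `kind`, `prepulse_level`, `startle_level`, `isi`, `gap_ms`)
#'   and session metadata (`condition`, `background_level`, `seed`,
#'   `session_min`).
#' @examples
#' plan <- build_session_plan(seed = 1, condition = "ppi")
#' table(plan$trials$kind[plan$trials$block == "paradigm"])
#' @export
build_session_plan <- function(seed = NULL,
                               condition = c("ppi", "startle_control", "background"),
                               n_startle_override = NULL,
                               background_level = 65,
                               startle_level = 110,
                               prepulse_levels = PPI_PREPULSE_LEVELS,
                               isi_range = c(1, 13),
                               prepulse_gap_ms = 100) {
  condition <- match.arg(condition)
  local_seed(seed)

  empty <- data.frame(
    trial = integer(), block = character(), kind = character(),
    prepulse_level = numeric(), startle_level = numeric(),
    isi = numeric(), gap_ms = numeric(), stringsAsFactors = FALSE
  )

  if (condition == "background") {
    plan <- list(trials = empty, condition = condition,
                 background_level = background_level, seed = seed,
                 session_min = 45)
    class(plan) <- "session_plan"
    return(plan)
  }

  make_block <- function(block, kind, prepulse, startle) {
    n <- length(kind)
    data.frame(
      trial = rep(NA_integer_, n), block = rep(block, n), kind = kind,
      prepulse_level = prepulse, startle_level = startle,
      isi = stats::runif(n, isi_range[1], isi_range[2]),
      gap_ms = ifelse(kind == "prepulse_startle", prepulse_gap_ms, NA_real_),
      stringsAsFactors = FALSE
    )
  }

  # Paradigm-block multiset for the PPI condition.
  kinds <- c(rep("background", 30),
             rep("startle_alone", 30),
             rep("prepulse_alone", 30 * length(prepulse_levels)),
             rep("prepulse_startle", 30 * length(prepulse_levels)))
  pp <- c(rep(NA_real_, 60),
          rep(prepulse_levels, each = 30),
          rep(prepulse_levels, each = 30))

  if (condition == "startle_control") {
    if (is.null(n_startle_override))
      stop_ppipet("startle_control sessions require n_startle_override")
    n_startle_override <- as.integer(n_startle_override)
    extra <- n_startle_override - 30L
    if (extra < 0L || extra > 120L)
      stop_ppipet("n_startle_override must lie in [30, 150]; got ",
                  n_startle_override)
    paired <- kinds == "prepulse_startle"
    repl <- c(rep("startle_alone", extra), rep("background", 120L - extra))
    kinds[paired] <- repl
    pp[paired] <- NA_real_
  }

  ord <- sample.int(length(kinds))
  paradigm <- make_block("paradigm", kinds[ord], pp[ord],
                         ifelse(kinds[ord] %in% c("startle_alone", "prepulse_startle"),
                                startle_level, NA_real_))

  habituation <- make_block("habituation", rep("startle_alone", 25),
                            rep(NA_real_, 25), rep(startle_level, 25))
  closing <- make_block("closing", rep("startle_alone", 20),
                        rep(NA_real_, 20), rep(startle_level, 20))

  trials <- rbind(habituation, paradigm, closing)
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL

  plan <- list(trials = trials, condition = condition,
               background_level = background_level, seed = seed,
               session_min = 45)
  class(plan) <- "session_plan"
  validate_session_plan(plan)
  plan
}

#' Validate a startle-session plan against the paradigm invariants
#'
#' Checks block sizes, the per-kind and per-level trial composition, the ISI
#' range and the prepulse-to-startle gap. Background sessions must be empty.
#'
#' @param plan A `session_plan`.
#' @return `plan`, invisibly; errors on violation.
#' @export
validate_session_plan <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  tr <- plan$trials
  if (plan$condition == "background") {
    if (nrow(tr) != 0L) stop_ppipet("background sessions carry no trials")
    return(invisible(plan))
  }
  if (sum(tr$block == "habituation") != 25L)
    stop_ppipet("habituation block must hold 25 startle-alone trials")
  if (sum(tr$block == "closing") != 20L)
    stop_ppipet("closing block must hold 20 startle-alone trials")
  par <- tr[tr$block == "paradigm", ]
  if (nrow(par) != 300L) stop_ppipet("paradigm block must hold 300 trials")
  if (any(tr$isi < 1 | tr$isi > 13)) stop_ppipet("ISI outside [1, 13] s")
  gap <- par$gap_ms[par$kind == "prepulse_startle"]
  if (length(gap) && any(gap != 100)) stop_ppipet("paired-trial gap must be 100 ms")
  has_pp <- par$kind %in% c("prepulse_alone", "prepulse_startle")
  if (any(is.na(par$prepulse_level[has_pp])) ||
      any(!is.na(par$prepulse_level[!has_pp])))
    stop_ppipet("prepulse level must be present iff the trial has a prepulse")
  if (plan$condition == "ppi") {
    if (sum(par$kind == "background") != 30L ||
        sum(par$kind == "startle_alone") != 30L ||
        sum(par$kind == "prepulse_alone") != 120L ||
        sum(par$kind == "prepulse_startle") != 120L)
      stop_ppipet("paradigm composition must be 30/30/120/120")
    for (k in c("prepulse_alone", "prepulse_startle")) {
      cnt <- table(par$prepulse_level[par$kind == k])
      if (any(cnt != 30L))
        stop_ppipet("each prepulse level needs 30 ", k, " trials")
    }
  }
  invisible(plan)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> condition=%s, %d trials (seed=%s)\n",
              x$condition, nrow(x$trials),
              if (is.null(x$seed)) "none" else x$seed))
  if (nrow(x$trials)) print(table(x$trials$block, x$trials$kind))
  invisible(x)
}
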