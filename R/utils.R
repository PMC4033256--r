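# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seed the RNG for the calling function and restore the previous state when
# the caller exits. seed = NULL leaves the active RNG stream untouched so
# callers can embed generators in an outer seeded simulation.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Derive a well-separated child seed from a master seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stop_ppipet <- function(..., class = "ppipet_error") {
  stop(errorCondition(paste0(...), class = c(class, "ppipet_error")))
}
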