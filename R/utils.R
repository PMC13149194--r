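# Internal helpers: time-unit arithmetic, seeded evaluation, rounding.

# 1 month = 365.25/12 days; the model cycle is 28 days.
DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25

months_to_days <- function(m) m * DAYS_PER_MONTH
days_to_months <- function(d) d / DAYS_PER_MONTH

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for reported monetary values, as
#' opposed to R's banker's rounding. Internal arithmetic is always kept at
#' full precision; this is applied only when formatting results.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a local RNG seed without disturbing global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
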