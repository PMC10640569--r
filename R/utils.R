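#' @useDynLib netpercolate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef fitted lm median pf predict quantile residuals rnorm
#'   runif sd setNames
NULL

# Round half away from zero (edge counts must match across implementations;
# base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded helpers do not perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a per-unit seed from a master seed by multiplicative splitting.
# Stays below 2^31 - 1; never reused across units for distinct idx.
derive_seed <- function(master_seed, idx) {
  m <- 2147483647
  as.integer((((master_seed %% m) * 48271) %% m + (idx * 69621) %% m) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
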