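# Internal numerical and RNG helpers.

# log(exp(x) + exp(y)) without overflow; vectorized.
logaddexp <- function(x, y) {
  m <- pmax(x, y)
  r <- m + log1p(exp(pmin(x, y) - m))
  # both -Inf -> -Inf, not NaN
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# sign with ties mapped to +1 (used where a direction must always exist)
sign_pos <- function(x) ifelse(x >= 0, 1, -1)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic counter-based fan-out so that pipeline stages (and datasets
#' within a stage) are independently reproducible from one global seed.
#' Results stay within the 32-bit integer range R requires of `set.seed`.
#'
#' @param seed Parent integer seed.
#' @param k Non-negative counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + (as.numeric(k) + 1) * 16807
  as.integer(s %% 2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
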