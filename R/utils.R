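# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting percent metrics (base R `round()` rounds
#' half to even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round the rational number 100 * num / den to 2 decimals, half up, using
# integer arithmetic only (exact for the counts that arise from confusion
# matrices).
round_percent_exact <- function(num, den) {
  stopifnot(den > 0)
  s <- sign(num)
  n4 <- floor((2 * 10000 * abs(num) + den) / (2 * den)) # half-up on |x|*100*100
  s * n4 / 100
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Clip a numeric vector to [lower, upper].
clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)

stop_ecgarr <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
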