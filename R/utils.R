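#' Round half away from zero
#'
#' Decimal rounding where exact halves move away from zero (so 10.25 with one
#' decimal becomes 10.3, not 10.2 as under banker's rounding). Used for all
#' reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Report a count as a percentage of a total
#'
#' @param count numeric count(s).
#' @param total denominator (> 0).
#' @param digits decimals for the rounded value.
#' @return numeric percentage rounded half away from zero; the raw fraction is
#'   attached as attribute `"fraction"`.
#' @export
report_percentage <- function(count, total, digits = 1) {
  if (total <= 0) stop("`total` must be positive")
  frac <- count / total
  out <- round_half_up(100 * frac, digits)
  attr(out, "fraction") <- frac
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# local RNG scope: honours `seed` if given (restoring the caller's stream);
# with seed = NULL the global stream is used and advanced as usual
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
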