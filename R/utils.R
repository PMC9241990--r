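## Small numerical helpers shared across the package.

## Probabilities of exactly zero occur throughout (deterministic likelihood and
## transition entries), so every logarithm goes through a floor.
.LOG_FLOOR <- 1e-16

#' Floored natural logarithm
#'
#' Natural log with a 1e-16 additive floor, so that deterministic (zero)
#' probability entries yield a large negative number rather than -Inf.
#'
#' @param x Numeric vector of probabilities (nonnegative).
#' @return `log(x + 1e-16)`.
#' @keywords internal
log_safe <- function(x) log(x + .LOG_FLOOR)

#' Softmax
#'
#' Numerically stable softmax \eqn{\sigma(x)_i = e^{x_i} / \sum_j e^{x_j}}.
#' This is the operator used for policy priors and posteriors.
#'
#' @param x Numeric vector of log-scale scores.
#' @return Probability vector of the same length, summing to one.
#' @export
#' @examples
#' softmax(c(0, -1))
softmax <- function(x) {
  y <- exp(x - max(x))
  y / sum(y)
}

## Normalize a nonnegative vector to sum to one; guards all-zero input.
normalize <- function(x) {
  s <- sum(x)
  if (s <= 0) rep(1 / length(x), length(x)) else x / s
}

## Column entropies -sum_o p ln p of a likelihood matrix (outcomes x states).
col_entropy <- function(A) {
  -colSums(A * log_safe(A))
}

## Check that every column of a matrix sums to one.
stopifnot_stochastic <- function(A, tol = 1e-10, what = "array") {
  if (any(abs(colSums(A) - 1) > tol)) {
    stop("columns of ", what, " do not sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

## Draw one index from a probability vector using a uniform deviate.
sample_index <- function(p) {
  u <- stats::runif(1)
  cs <- cumsum(p / sum(p))
  findInterval(u, cs) + 1L
}
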