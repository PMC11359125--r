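#' Mean and population variance of a sample
#'
#' Computes the arithmetic mean and the population variance (divisor
#' \code{n}, not \code{n - 1}).  The population form is the one used to
#' summarise per-bin saccade counts in the attention-index system, where the
#' bins of one evaluation window are the whole population of interest.
#'
#' @param x Numeric vector, length at least 1, no missing values.
#' @return Named list with elements \code{mean} and \code{variance}.
#' @examples
#' mean_and_variance(c(1, 2, 3))  # mean 2, variance 2/3
#' @export
mean_and_variance <- function(x) {
  if (length(x) < 1L) stop("mean_and_variance: sample must contain at least one value")
  if (anyNA(x)) stop("mean_and_variance: missing values are not allowed")
  x <- as.numeric(x)
  m <- sum(x) / length(x)
  list(mean = m, variance = sum((x - m)^2) / length(x))
}

#' Spearman rank correlation with average-rank ties
#'
#' Assigns average ranks to \code{x} and \code{y} and applies the
#' product-moment correlation formula to the ranks.  This is the rank-based
#' monotone association coefficient used to relate attention indicators to
#' attention level; ties (frequent when the grouping variable takes only a
#' few levels) receive the average of the ranks they span.
#'
#' @param x,y Numeric vectors of equal length, at least 2, no missing values.
#' @return Correlation value in \code{[-1, 1]}.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))  # 1: perfect monotone
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: x and y must have equal length")
  if (length(x) < 2L) stop("spearman_rho: need at least two pairs")
  if (anyNA(x) || anyNA(y)) stop("spearman_rho: missing values are not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("spearman_rho: correlation undefined for a constant variable")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Permutation p-value for the Spearman correlation
#'
#' Two-sided permutation test: the proportion of label permutations whose
#' absolute Spearman coefficient is at least the observed one.
#'
#' @param x,y Numeric vectors as in [spearman_rho()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return List with \code{rho} and \code{p_value}.
#' @export
spearman_perm_test <- function(x, y, n_perm = 10000L, seed = 1L) {
  rho <- spearman_rho(x, y)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- spearman_rho(x, sample(y))
    if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  list(rho = rho, p_value = (hits + 1L) / (n_perm + 1L))
}
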