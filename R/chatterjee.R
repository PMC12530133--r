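#' Chatterjee's rank correlation coefficient
#'
#' Estimates the rank correlation \eqn{\xi_n(X, Y)}: order the sample by `x`,
#' take the ranks \eqn{r_i} of the corresponding `y` values, and compute
#' \deqn{1 - \frac{3\sum_{i=1}^{n-1} |r_{i+1} - r_i|}{n^2 - 1}}
#' in the tie-free case. With ties in `y` the general tie-aware form
#' \deqn{1 - \frac{n \sum_{i=1}^{n-1} |r_{i+1} - r_i|}{2 \sum_i l_i (n - l_i)}}
#' is used, where \eqn{r_i = \#\{j : y_j \le y_{(i)}\}} and
#' \eqn{l_i = \#\{j : y_j \ge y_{(i)}\}}. Ties in `x` are broken uniformly at
#' random (controlled by `seed`). The estimator is asymmetric in its
#' arguments, lies in `[-1/2, 1]` in sample, and is invariant to strictly
#' increasing transforms of each margin; negative values indicate alternating
#' `y` along the `x` order (non-i.i.d. structure).
#'
#' @param x,y Numeric vectors of equal length (n >= 2). The coefficient
#'   measures how well `y` is a function of `x`.
#' @param seed Optional seed for the random tie-break among `x` values.
#' @return An [assoc_value()] with `direction = "xy"`.
#' @examples
#' chatterjee(1:5, c(1, 5, 2, 4, 3))$value  # -0.25
#' @export
chatterjee <- function(x, y, seed = NULL) {
  x <- as_uni(x, "x"); y <- as_uni(y, "y")
  n <- check_xy(x, y)
  if (length(unique(y)) == 1L) {
    warning("`y` is constant; Chatterjee coefficient defined as 0")
    return(assoc_value("chatterjee", "xy", 0, n))
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- order(x, stats::runif(n))       # random tie-break among equal x
  yo <- y[ord]
  r <- rank(yo, ties.method = "max")     # r_i = #{j : y_j <= y_(i)}
  l <- n + 1L - rank(yo, ties.method = "min")  # l_i = #{j : y_j >= y_(i)}
  num <- as.numeric(n) * sum(abs(diff(r)))
  den <- 2 * sum(as.numeric(l) * (n - l))
  assoc_value("chatterjee", "xy", 1 - num / den, n)
}

#' Symmetrized Chatterjee coefficient
#'
#' `max(xi(X, Y), xi(Y, X))`, the usual symmetrization of an asymmetric
#' association measure.
#'
#' @inheritParams chatterjee
#' @return An [assoc_value()] with `direction = "sym"`.
#' @export
chatterjee_sym <- function(x, y, seed = NULL) {
  xy <- chatterjee(x, y, seed = seed)
  yx <- chatterjee(y, x, seed = seed)
  assoc_value("chatterjee", "sym", max(xy$value, yx$value), xy$n)
}
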