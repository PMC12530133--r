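#' Distance correlation (V-statistic form)
#'
#' Sample distance correlation between `X` in R^p and `Y` in R^q, from the
#' double-centered Euclidean distance matrices
#' \deqn{dCov_n^2(X, Y) = \frac{1}{n^2}\sum_{j,k} A_{jk} B_{jk}, \qquad
#'       \rho_n = \frac{dCov_n(X,Y)}{\sqrt{dCov_n(X,X)\,dCov_n(Y,Y)}},}
#' where \eqn{A_{jk}} (resp. \eqn{B_{jk}}) is the pairwise distance matrix of
#' `x` (resp. `y`) with row, column and grand means swept out. The biased
#' V-statistic normalization `1/n^2` is used throughout. The coefficient is
#' symmetric and lies in `[0, 1]`; it equals 1 when `y` is an affine isometry
#' of `x`, and is 0 when either marginal distance variance vanishes
#' (degenerate margin, reported with a warning). It is a measure of general
#' dependence but notably not invariant to monotone marginal transforms, and
#' for `Y = |X|` with `X` symmetric about 0 it is bounded by \eqn{2^{-1/4}}.
#'
#' @param x,y Numeric vectors or matrices with the same number of rows
#'   (n >= 3).
#' @return An [assoc_value()] with `direction = "sym"`.
#' @examples
#' z <- rnorm(100)
#' dcor(z, 2 * z + 1)$value  # 1 (affine image)
#' @export
dcor <- function(x, y) {
  x <- as_sample_matrix(x, "x")
  y <- as_sample_matrix(y, "y")
  if (nrow(x) != nrow(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  A <- dcenter(pair_dist(x))
  B <- dcenter(pair_dist(y))
  vx <- mean(A * A)
  vy <- mean(B * B)
  if (vx <= .Machine$double.eps || vy <= .Machine$double.eps) {
    warning("degenerate margin (zero distance variance); distance correlation set to 0")
    return(assoc_value("dcor", "sym", 0, n))
  }
  v <- mean(A * B)
  val <- if (v <= 0) 0 else sqrt(v) / sqrt(sqrt(vx) * sqrt(vy))
  assoc_value("dcor", "sym", min(1, val), n)
}

pair_dist <- function(m) {
  if (ncol(m) == 1L) abs(outer(m[, 1L], m[, 1L], "-"))
  else as.matrix(stats::dist(m))
}

dcenter <- function(d) {
  rm <- rowMeans(d)
  d - outer(rm, rep(1, length(rm))) - outer(rep(1, length(rm)), rm) + mean(d)
}
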