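#' Maximal information coefficient (MIC)
#'
#' Estimates
#' \deqn{MIC(X,Y) = \max_{n_x n_y \le B} \frac{\max_G \hat I_{G}(X,Y)}
#'       {\log\min(n_x, n_y)},}
#' the largest grid-normalized mutual information over rectangular
#' `n_x x n_y` grids whose cell budget is bounded by
#' `B = floor(n^grid_exponent)`.
#'
#' The exact outer maximization is infeasible, so the standard MINE-style
#' approximation is used: one axis is equipartitioned (equal-frequency bins)
#' and the other axis' partition is optimized exactly by dynamic programming
#' over `clump_factor * n_bins` equal-frequency micro-bins; both orientations
#' are searched and the maximum taken. As a rank-based statistic MIC is
#' invariant to strictly increasing marginal transforms and lies in `[0, 1]`,
#' reaching 1 on noiseless functional (in particular bijective)
#' relationships.
#'
#' @param x,y Numeric vectors (n >= 20).
#' @param grid_exponent Budget exponent; default 0.6 (the customary
#'   `n^0.6` bound on `n_x * n_y`).
#' @param clump_factor Micro-bin multiplier for the DP axis (default 5);
#'   larger values search finer candidate cut points at quadratic cost.
#' @return An [assoc_value()] with `direction = "sym"`.
#' @examples
#' x <- runif(200)
#' mic(x, x)$value  # ~1
#' @export
mic <- function(x, y, grid_exponent = 0.6, clump_factor = 5L) {
  x <- as_uni(x, "x"); y <- as_uni(y, "y")
  n <- check_xy(x, y, min_n = 20L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant margin; MIC set to 0")
    return(assoc_value("mic", "sym", 0, n))
  }
  B <- floor(n^grid_exponent)
  if (B < 4L) B <- 4L
  best <- 0
  for (swap in c(FALSE, TRUE)) {
    u <- if (swap) y else x
    v <- if (swap) x else y
    ord_u <- order(u, stats::runif(n)) - 1L          # random tie-break
    for (q in 2:max(2L, B %/% 2L)) {
      L <- B %/% q
      if (L < 2L) break
      vbin <- rank_bin(v, q) - 1L
      I <- .mic_axis_dp(ord_u, vbin, q, L, as.integer(clump_factor))
      for (l in 2:L) {
        val <- I[l + 1L] / log(min(l, q))
        if (is.finite(val) && val > best) best <- val
      }
    }
  }
  assoc_value("mic", "sym", min(1, best), n,
              params = list(grid_exponent = grid_exponent,
                            clump_factor = clump_factor))
}
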