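#' Pearson and Spearman correlation as association values
#'
#' Thin wrappers around [stats::cor()] returning the shared [assoc_value()]
#' container, so the classical linear / monotone baselines can be plugged
#' into the same cluster-weighting machinery as the nonlinear measures.
#'
#' @param x,y Numeric vectors of equal length.
#' @return An [assoc_value()] with `direction = "sym"` and value in
#'   `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  x <- as_uni(x, "x"); y <- as_uni(y, "y")
  n <- check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant margin; Pearson correlation set to 0")
    return(assoc_value("pearson", "sym", 0, n))
  }
  assoc_value("pearson", "sym", stats::cor(x, y), n)
}

#' @rdname pearson_corr
#' @export
spearman_corr <- function(x, y) {
  x <- as_uni(x, "x"); y <- as_uni(y, "y")
  n <- check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant margin; Spearman correlation set to 0")
    return(assoc_value("spearman", "sym", 0, n))
  }
  assoc_value("spearman", "sym", stats::cor(x, y, method = "spearman"), n)
}

#' Compute a named association measure
#'
#' Uniform entry point dispatching to the individual estimators; this is what
#' the cluster-weighted combination and the command-line interface call for
#' each cluster.
#'
#' Measures `"chatterjee"` and `"copula"` are directional; with `sym = TRUE`
#' the symmetrized `max` of the two directions is returned. `"dcor"` accepts
#' multivariate `x` / `y`; the remaining measures are univariate and use the
#' first column with a warning if more are supplied.
#'
#' @param x,y Numeric vectors or matrices with matching rows.
#' @param measure One of `"pearson"`, `"spearman"`, `"chatterjee"`,
#'   `"dcor"`, `"maximal"`, `"mic"`, `"copula"`.
#' @param sym Symmetrize directional measures? Default `FALSE`.
#' @param params Named list of estimator parameters passed through (e.g.
#'   `bandwidth` for `"maximal"`, `resolution` for `"copula"`).
#' @return An [assoc_value()].
#' @examples
#' association(rnorm(50), rnorm(50), "chatterjee")
#' @export
association <- function(x, y,
                        measure = c("pearson", "spearman", "chatterjee",
                                    "dcor", "maximal", "mic", "copula"),
                        sym = FALSE, params = list()) {
  measure <- match.arg(measure)
  if (measure == "dcor") return(do.call(dcor, c(list(x, y), params)))
  x <- first_col(x); y <- first_col(y)
  if (measure == "chatterjee") {
    f <- if (sym) chatterjee_sym else chatterjee
    return(do.call(f, c(list(x, y), params)))
  }
  if (measure == "copula") {
    if (!sym) return(do.call(copula_corr, c(list(x, y), params)))
    a <- do.call(copula_corr, c(list(x, y), params))
    b <- do.call(copula_corr, c(list(y, x), params))
    return(assoc_value("copula", "sym", max(a$value, b$value), a$n, a$params))
  }
  f <- switch(measure, pearson = pearson_corr, spearman = spearman_corr,
              maximal = maximal_corr, mic = mic)
  do.call(f, c(list(x, y), params))
}

first_col <- function(v) {
  if (is.matrix(v) || is.data.frame(v)) {
    if (ncol(v) > 1L) warning("univariate measure: using first column only")
    as.numeric(v[, 1L])
  } else as.numeric(v)
}
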