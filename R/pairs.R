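#' Paired sample container
#'
#' Bundles `n` joint observations of `X` (in R^p) and `Y` (in R^q) as the
#' common input of every association estimator and clustering routine in the
#' package.
#'
#' @param x Numeric matrix or vector of X observations (rows = observations).
#' @param y Numeric matrix or vector of Y observations; must have the same
#'   number of rows as `x`.
#' @return An object of class `paired_sample`: a list with matrices `x` and
#'   `y` and the sample size `n`.
#' @examples
#' ps <- paired_sample(rnorm(10), rnorm(10))
#' ps$n
#' @export
paired_sample <- function(x, y) {
  x <- as_sample_matrix(x, "x")
  y <- as_sample_matrix(y, "y")
  if (nrow(x) != nrow(y)) {
    stop("`x` and `y` must have the same number of observations", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  structure(list(x = x, y = y, n = nrow(x)), class = "paired_sample")
}

#' Paired sample with ground-truth component labels
#'
#' A [paired_sample()] whose points carry the index of the mixture component
#' that generated them. Label `0` is reserved for ambient noise.
#'
#' @param x,y As in [paired_sample()].
#' @param true_labels Integer vector of component labels, one per observation;
#'   values in `{0, 1, ..., K}` with 0 meaning ambient noise.
#' @return An object of class `labeled_sample` (inherits `paired_sample`).
#' @export
labeled_sample <- function(x, y, true_labels) {
  ps <- paired_sample(x, y)
  true_labels <- as.integer(true_labels)
  if (length(true_labels) != ps$n) {
    stop("`true_labels` must have one entry per observation", call. = FALSE)
  }
  if (any(true_labels < 0L)) stop("labels must be >= 0", call. = FALSE)
  ps$true_labels <- true_labels
  class(ps) <- c("labeled_sample", "paired_sample")
  ps
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> n = %d, p = %d, q = %d\n",
              x$n, ncol(x$x), ncol(x$y)))
  if (!is.null(x$true_labels)) {
    tab <- table(x$true_labels)
    cat("  components:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Joint coordinate matrix of a paired sample
#'
#' Concatenates the X and Y blocks column-wise, giving the (p+q)-dimensional
#' point cloud that the clustering algorithms operate on.
#'
#' @param pairs A [paired_sample()].
#' @return Numeric matrix with `n` rows and `p + q` columns.
#' @export
joint_points <- function(pairs) {
  stopifnot(inherits(pairs, "paired_sample"))
  cbind(pairs$x, pairs$y)
}

as_sample_matrix <- function(v, name) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (!is.matrix(v)) v <- matrix(as.numeric(v), ncol = 1L)
  storage.mode(v) <- "double"
  if (!all(is.finite(v))) {
    stop(sprintf("`%s` must contain only finite values", name), call. = FALSE)
  }
  v
}

# single numeric column, for the univariate estimators
as_uni <- function(v, name) {
  if (inherits(v, "paired_sample")) {
    stop("pass plain vectors; extract columns from the paired_sample", call. = FALSE)
  }
  v <- as.numeric(v)
  if (!all(is.finite(v))) {
    stop(sprintf("`%s` must contain only finite values", name), call. = FALSE)
  }
  v
}

check_xy <- function(x, y, min_n = 2L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < min_n) {
    stop(sprintf("need at least %d observations", min_n), call. = FALSE)
  }
  invisible(length(x))
}

#' Association estimate container
#'
#' @param measure Measure name, e.g. `"chatterjee"`, `"dcor"`, `"maximal"`.
#' @param direction One of `"xy"`, `"yx"`, `"sym"`.
#' @param value The estimate.
#' @param n Sample size it was computed from.
#' @param params Optional named list of estimator parameters.
#' @return An object of class `assoc_value`.
#' @export
assoc_value <- function(measure, direction, value, n, params = list()) {
  structure(
    list(measure = measure, direction = direction, value = as.numeric(value),
         n = as.integer(n), params = params),
    class = "assoc_value"
  )
}

#' @export
print.assoc_value <- function(x, ...) {
  cat(sprintf("%s (%s): %.4f  [n = %d]\n", x$measure, x$direction, x$value, x$n))
  invisible(x)
}

#' @export
as.numeric.assoc_value <- function(x, ...) x$value
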