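#' Density-sensitive path-distance transforms
#'
#' Constructor for the edge-length transform `g` used by the interpolating
#' path distance [g_distance_matrix()]. `g` must be continuous, strictly
#' increasing, strictly super-additive and satisfy `g(0) = 0`; the two
#' standard families are the power family `g(t) = t^s` (`s > 1`) and the
#' exponential family `g(t) = exp(a t) - 1` (`a > 0`). Large `s` (or `a`)
#' pushes the path distance toward the minimax longest-leg distance; `s`
#' (or `a`) near its lower limit recovers Euclidean shortest paths.
#'
#' @param name `"power"` or `"exponential"`.
#' @param param `s > 1` for the power family, `a > 0` for the exponential.
#' @return An object of class `g_function` with fields `name`, `param`,
#'   `fun` and `inv`.
#' @examples
#' g <- g_function("power", 10)
#' g$inv(g$fun(0.3))  # 0.3
#' @export
g_function <- function(name = c("power", "exponential"), param) {
  name <- match.arg(name)
  if (name == "power") {
    if (param <= 1) stop("power family requires s > 1", call. = FALSE)
    fun <- function(t) t^param
    inv <- function(t) t^(1 / param)
  } else {
    if (param <= 0) stop("exponential family requires a > 0", call. = FALSE)
    fun <- function(t) expm1(param * t)
    inv <- function(t) log1p(t) / param
  }
  structure(list(name = name, param = param, fun = fun, inv = inv),
            class = "g_function")
}

#' Longest-leg path distance (LLPD) matrix
#'
#' Pairwise minimax path distance through the sample: for points `a`, `b`,
#' the minimum over all paths `a = z_0, z_1, ..., z_{r+1} = b` through sample
#' points of the longest Euclidean edge on the path. Within a dense cluster
#' the LLPD collapses to the nearest-neighbor scale while between separated
#' clusters it stays at least the separation gap, which is what makes it
#' density-sensitive. The LLPD is an ultrametric:
#' `LLPD(a,c) <= max(LLPD(a,b), LLPD(b,c))`.
#'
#' Computed as the maximum edge on the unique path of a Euclidean minimum
#' spanning tree, via single-linkage merging of the sorted MST edges.
#'
#' @param points Numeric matrix (rows = points, n >= 2).
#' @return A `clam_dist` object: list with the symmetric matrix `d` and
#'   `kind = "llpd"`.
#' @export
llpd_matrix <- function(points) {
  points <- as_sample_matrix(points, "points")
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  ed <- as.matrix(stats::dist(points))
  mst <- euclid_mst(ed)
  d <- matrix(0, n, n)
  # Kruskal-style merge: when an edge of weight w joins two components,
  # every cross pair's minimax path distance equals w
  comp <- as.list(seq_len(n))
  comp_id <- seq_len(n)
  for (k in order(mst$w)) {
    a <- comp_id[mst$i[k]]; b <- comp_id[mst$j[k]]
    if (a == b) next
    ia <- comp[[a]]; ib <- comp[[b]]
    d[ia, ib] <- mst$w[k]
    d[ib, ia] <- mst$w[k]
    comp[[a]] <- c(ia, ib)
    comp_id[ib] <- a
    comp[b] <- list(NULL)
  }
  structure(list(d = d, kind = "llpd"), class = "clam_dist")
}

#' Interpolating g-distance matrix
#'
#' Pairwise path distance with transformed edge lengths:
#' \deqn{L_g(a, b) = g^{-1}\Big(\min_p \sum_i g\big(e(z_i, z_{i+1})\big)\Big),}
#' the shortest-path distance in the complete Euclidean graph after applying
#' `g` to every edge, mapped back through `g^{-1}`. For super-additive `g`
#' this interpolates between the Euclidean distance (mild `g`) and the
#' longest-leg path distance (extreme `g`), and always satisfies
#' `LLPD <= L_g <= Euclidean`.
#'
#' For the homogeneous power family the edges are rescaled by their maximum
#' before transforming and the result scaled back (exact, since
#' `L_g(c x) = c L_g(x)`), which avoids overflow at large exponents; the
#' exponential family is evaluated in the log domain the same way via the
#' identity on `expm1`/`log1p`.
#'
#' @param points Numeric matrix (rows = points).
#' @param g A [g_function()].
#' @return A `clam_dist` object with `kind = "g"`.
#' @export
g_distance_matrix <- function(points, g) {
  points <- as_sample_matrix(points, "points")
  stopifnot(inherits(g, "g_function"))
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  ed <- as.matrix(stats::dist(points))
  scale <- max(ed)
  if (scale == 0) {
    return(structure(list(d = ed, kind = "g"), class = "clam_dist"))
  }
  a <- g$param
  if (g$name == "exponential" && a * scale > 700) {
    # expm1 would overflow; at this regime the max edge dominates the path
    # sum and the distance is numerically the longest-leg path distance
    warning("exponential g saturates at this scale; clamping to exp(700) regime")
    a <- 700 / scale
  }
  w <- if (g$name == "power") (ed / scale)^a else expm1(a * ed)
  gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  sp <- igraph::distances(gr, algorithm = "dijkstra")
  d <- if (g$name == "power") sp^(1 / a) * scale else log1p(sp) / a
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- NULL
  structure(list(d = d, kind = "g"), class = "clam_dist")
}

#' @export
print.clam_dist <- function(x, ...) {
  cat(sprintf("<clam_dist> %d x %d, kind = %s\n", nrow(x$d), ncol(x$d), x$kind))
  invisible(x)
}

# MST edge list from a dense distance matrix, via igraph
euclid_mst <- function(ed) {
  gr <- igraph::graph_from_adjacency_matrix(ed, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  tr <- igraph::mst(gr, algorithm = "prim")
  el <- igraph::as_edgelist(tr, names = FALSE)
  list(i = el[, 1L], j = el[, 2L], w = igraph::E(tr)$weight)
}
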