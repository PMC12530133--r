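#' Neighborhood-graph clustering with denoising
#'
#' The two-parameter consistency-guaranteed clustering: first denoise by
#' keeping only core points whose `s`-th nearest neighbor lies within radius
#' `r`, then connect kept points at distance `<= r` and take connected
#' components as clusters. Under a mixture of densities on disjoint
#' low-dimensional manifolds with separation `delta`, any
#' `r` between the within-manifold connectivity scale and `delta` recovers
#' the true components almost surely as `n` grows.
#'
#' Components smaller than `max(3, s)` are relabeled as noise, since
#' association measures are meaningless on a couple of points.
#'
#' @param points Numeric matrix of observations (rows), or a
#'   [paired_sample()] whose joint (x, y) coordinates are clustered.
#' @param r Neighborhood radius (> 0).
#' @param s Denoising neighbor count (>= 1); default `ceiling(log(n))`.
#' @return An object of class `clam_clusters`: `labels` (length n; `-1` =
#'   noise/denoised), `K`, `algorithm = "NG"`, `sizes`, and `params`.
#' @examples
#' b <- gen_two_blocks(300, seed = 1)
#' cl <- ng_clusters(b, r = 0.5, s = 3)
#' cl$K  # 2
#' @export
ng_clusters <- function(points, r, s = NULL) {
  pts <- cluster_input(points)
  n <- nrow(pts)
  if (is.null(s)) s <- ceiling(log(n))
  s <- check_count(s, 1L)
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("`r` must be a positive radius", call. = FALSE)
  }
  if (n <= s) stop("need n > s observations", call. = FALSE)
  ed <- as.matrix(stats::dist(pts))
  kth <- apply(ed, 1L, function(d) sort(d, partial = s + 1L)[s + 1L])
  keep <- which(kth <= r)
  labels <- rep(-1L, n)
  K <- 0L
  if (length(keep) >= 2L) {
    adj <- ed[keep, keep, drop = FALSE] <= r
    diag(adj) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(gr)$membership
    labels[keep] <- relabel_components(memb, min_size = max(3L, s))
    K <- max(0L, labels)
  }
  if (K == 0L) warning("all points denoised or in sub-minimum components; no clusters")
  new_clusters(labels, "NG", params = list(r = r, s = s))
}

#' Cluster-count selection by the eigengap heuristic
#'
#' Picks `k` as the location of the largest gap in the ascending Laplacian
#' spectrum: `argmax_{1 <= k <= kmax} (lambda_{k+1} - lambda_k)`, ties broken
#' toward the smaller `k`. In the ideal separated case the smallest `K`
#' eigenvalues of the symmetric normalized Laplacian are 0 and the rest 1,
#' so the heuristic returns the true component count.
#'
#' @param eigenvalues Numeric vector of eigenvalues sorted ascending.
#' @param kmax Largest candidate `k`; needs `length(eigenvalues) >= kmax + 1`.
#' @return Integer `k`.
#' @examples
#' eigengap_k(c(0, 0, 0, 1, 1, 1), kmax = 5)  # 3
#' @export
eigengap_k <- function(eigenvalues, kmax) {
  kmax <- check_count(kmax, 1L)
  if (length(eigenvalues) < kmax + 1L) {
    stop("need at least kmax + 1 eigenvalues", call. = FALSE)
  }
  if (is.unsorted(eigenvalues, strictly = FALSE)) {
    stop("`eigenvalues` must be sorted ascending", call. = FALSE)
  }
  gaps <- diff(eigenvalues)[seq_len(kmax)]
  which.max(gaps)   # first maximum = smallest k on ties
}

#' Spectral clustering with density-sensitive distances and eigengap
#'
#' The second consistency-guaranteed procedure: denoise (as in
#' [ng_clusters()], with radius `sigma`), compute the longest-leg path
#' distance or the interpolating g-distance among kept points, form the
#' Gaussian affinity `W_ij = exp(-d_ij^2 / sigma^2)` (any kernel vanishing
#' beyond the separation and tending to 1 at 0 satisfies the theory), take
#' the symmetric normalized Laplacian
#' `L_sym = I - D^{-1/2} W D^{-1/2}`, choose the number of clusters by
#' [eigengap_k()] on its spectrum, embed the points in the `k` eigenvectors
#' of smallest eigenvalue with row normalization, and partition the rows by
#' k-means with multi-restart.
#'
#' @param points Numeric matrix or [paired_sample()].
#' @param distance `"llpd"` or `"g"`.
#' @param sigma Affinity scale and denoising radius (> 0).
#' @param g A [g_function()] (required when `distance = "g"`).
#' @param s Denoising neighbor count; default `ceiling(log(n))`.
#' @param kmax Largest candidate cluster count; default `ceiling(sqrt(n))`.
#' @param seed Seed for the k-means restarts (default 1), making the
#'   partition deterministic.
#' @return A `clam_clusters` object with `algorithm = "SC"` and the sorted
#'   Laplacian spectrum head in `$eigenvalues`.
#' @examples
#' b <- gen_two_blocks(200, seed = 1)
#' sc <- spectral_cluster(b, distance = "g", sigma = 1,
#'                        g = g_function("power", 10))
#' sc$K  # 2
#' @export
spectral_cluster <- function(points, distance = c("llpd", "g"), sigma,
                             g = NULL, s = NULL, kmax = NULL, seed = 1L) {
  pts <- cluster_input(points)
  distance <- match.arg(distance)
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scale", call. = FALSE)
  }
  if (distance == "g" && !inherits(g, "g_function")) {
    stop("`g` must be a g_function() when distance = \"g\"", call. = FALSE)
  }
  if (is.null(s)) s <- ceiling(log(n))
  s <- check_count(s, 1L)

  ed <- as.matrix(stats::dist(pts))
  kth <- apply(ed, 1L, function(d) sort(d, partial = s + 1L)[s + 1L])
  keep <- which(kth <= sigma)
  labels <- rep(-1L, n)
  params <- list(distance = distance, sigma = sigma, s = s,
                 kernel = "gaussian",
                 g = if (!is.null(g)) list(name = g$name, param = g$param))
  if (length(keep) < 4L) {
    warning("fewer than 4 points survive denoising; no clusters")
    return(new_clusters(labels, "SC", params))
  }
  kept_pts <- pts[keep, , drop = FALSE]
  dm <- if (distance == "llpd") llpd_matrix(kept_pts)
        else g_distance_matrix(kept_pts, g)
  m <- length(keep)
  W <- exp(-(dm$d / sigma)^2)
  diag(W) <- 1
  deg <- rowSums(W)
  isolated <- deg <= .Machine$double.eps
  if (any(isolated)) {                      # zero-degree vertices become noise
    keep <- keep[!isolated]
    kept_pts <- kept_pts[!isolated, , drop = FALSE]
    W <- W[!isolated, !isolated, drop = FALSE]
    deg <- rowSums(W)
    m <- length(keep)
  }
  dhalf <- 1 / sqrt(deg)
  L <- diag(m) - (dhalf * W) %*% diag(dhalf)
  L <- (L + t(L)) / 2
  es <- eigen(L, symmetric = TRUE)
  lam <- rev(es$values)                      # ascending
  if (is.null(kmax)) kmax <- ceiling(sqrt(m))
  kmax <- min(check_count(kmax, 1L), m - 1L)
  khat <- eigengap_k(lam, kmax)
  if (khat == 1L) {
    memb <- rep(1L, m)
  } else {
    emb <- es$vectors[, m - seq_len(khat) + 1L, drop = FALSE]
    rn <- sqrt(rowSums(emb^2))
    rn[rn == 0] <- 1
    emb <- emb / rn
    memb <- with_seed(seed, stats::kmeans(emb, centers = khat, nstart = 10L,
                                          iter.max = 50L)$cluster)
  }
  labels[keep] <- relabel_components(memb, min_size = max(3L, s))
  res <- new_clusters(labels, "SC", params)
  res$eigenvalues <- lam[seq_len(min(m, kmax + 1L))]
  res$khat <- khat
  res
}

# shared construction/cleanup -------------------------------------------------

new_clusters <- function(labels, algorithm, params) {
  K <- max(0L, labels)
  sizes <- if (K > 0L) tabulate(labels[labels > 0L], nbins = K) else integer(0)
  structure(list(labels = labels, K = K, algorithm = algorithm,
                 sizes = sizes, params = params),
            class = "clam_clusters")
}

#' @export
print.clam_clusters <- function(x, ...) {
  cat(sprintf("<clam_clusters> %s: K = %d, n = %d (%d noise)\n",
              x$algorithm, x$K, length(x$labels), sum(x$labels == -1L)))
  if (x$K > 0L) cat("  sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

cluster_input <- function(points) {
  if (inherits(points, "paired_sample")) joint_points(points)
  else as_sample_matrix(points, "points")
}

# renumber components 1..K by decreasing size; components below min_size -> -1
relabel_components <- function(memb, min_size) {
  sizes <- table(memb)
  good <- names(sizes)[sizes >= min_size]
  good <- good[order(-sizes[good], as.numeric(good))]
  out <- rep(-1L, length(memb))
  for (k in seq_along(good)) out[memb == good[k]] <- k
  out
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
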