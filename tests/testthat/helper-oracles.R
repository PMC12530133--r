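# Brute-force minimax / g-domain shortest paths over all simple paths,
# independent of the MST / Dijkstra implementations (feasible for n <= 8).
brute_path_matrix <- function(ed, g = NULL) {
  n <- nrow(ed)
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(r) c(v[i], r))))
  }
  out <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    best <- Inf
    mids <- setdiff(seq_len(n), c(a, b))
    for (k in 0:length(mids)) {
      combs <- if (k == 0L) list(integer(0)) else utils::combn(mids, k, simplify = FALSE)
      for (cmb in combs) for (pm in all_perms(cmb)) {
        path <- c(a, pm, b)
        e <- ed[cbind(path[-length(path)], path[-1L])]
        val <- if (is.null(g)) max(e) else g$inv(sum(g$fun(e)))
        if (val < best) best <- val
      }
    }
    out[a, b] <- out[b, a] <- best
  }
  out
}

# best-matching clustering accuracy over ALL points (noise counts as error)
cluster_accuracy <- function(labels, truth) {
  tot <- 0
  used <- character(0)
  for (k in sort(unique(truth))) {
    tab <- table(labels[truth == k & labels > 0L])
    tab <- tab[!(names(tab) %in% used)]
    if (length(tab)) {
      tot <- tot + max(tab)
      used <- c(used, names(tab)[which.max(tab)])
    }
  }
  tot / length(truth)
}

# exhaustive MIC for tiny samples: every axis partition of every grid shape
# within the n^0.6 budget (test oracle for the DP approximation)
mic_exhaustive <- function(x, y, grid_exponent = 0.6) {
  n <- length(x)
  B <- max(4L, floor(n^grid_exponent))
  ox <- order(x); oy <- order(y)
  rx <- integer(n); rx[ox] <- seq_len(n)
  ry <- integer(n); ry[oy] <- seq_len(n)
  info <- function(xb, yb) {
    tab <- table(xb, yb) / n
    px <- rowSums(tab); py <- colSums(tab)
    s <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
    }
    s
  }
  cuts_to_bins <- function(r, cuts) findInterval(r, c(0.5, cuts + 0.5, n + 0.5))
  best <- 0
  for (nx in 2:(B %/% 2L)) {
    ny_max <- B %/% nx
    if (ny_max < 2L) next
    xcuts <- utils::combn(seq_len(n - 1L), nx - 1L, simplify = FALSE)
    for (ny in 2:ny_max) {
      ycuts <- utils::combn(seq_len(n - 1L), ny - 1L, simplify = FALSE)
      for (xc in xcuts) for (yc in ycuts) {
        I <- info(cuts_to_bins(rx, xc), cuts_to_bins(ry, yc))
        val <- unname(I / log(min(nx, ny)))
        if (val > best) best <- val
      }
    }
  }
  best
}

# full-precision JSON serialization for byte-level determinism checks
serialize_result_for_test <- function(x) {
  jsonlite::toJSON(clamcor:::serialize_result(x), auto_unbox = TRUE, digits = NA)
}
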