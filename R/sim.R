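#' Bivariate Gaussian mixture with a rotating minority component
#'
#' Draws `n` points from
#' \deqn{(1-\alpha)\,N_2((0,0), I_2) + \alpha\,N_2((6\cos\theta, 6\sin\theta), I_2),}
#' the benchmark design in which the minority component's center rotates on a
#' circle of radius 6 around the origin. Because both covariances are the
#' identity, the distribution at fixed `alpha` is rotation-invariant in
#' `theta`, which is exactly the property a cluster-aware association measure
#' should respect and a whole-sample measure does not.
#'
#' Component membership is drawn per point as Bernoulli(`alpha`), not by
#' fixed-count stratification, so the realized minority fraction fluctuates
#' binomially around `alpha`.
#'
#' @param n Sample size (>= 2).
#' @param alpha Minority-component weight, strictly inside (0, 1).
#' @param theta Rotation angle of the minority center, in radians.
#' @param seed Optional integer seed; a fixed seed gives bit-identical output.
#' @return A [labeled_sample()] with `true_labels` 1 (majority) or 2 (minority).
#' @examples
#' s <- gen_gaussian_mixture(200, alpha = 0.1, theta = pi / 6, seed = 1)
#' table(s$true_labels)
#' @export
gen_gaussian_mixture <- function(n, alpha, theta, seed = NULL) {
  n <- check_count(n, 2L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- 1L + stats::rbinom(n, 1L, alpha)
  mu <- 6 * c(cos(theta), sin(theta))
  x <- stats::rnorm(n) + (lab == 2L) * mu[1L]
  y <- stats::rnorm(n) + (lab == 2L) * mu[2L]
  labeled_sample(x, y, lab)
}

#' Noisy functional relationships on the unit interval
#'
#' Generates `x ~ Unif[0,1]` and `y = m(x) + eps` with `eps ~ N(0, sigma^2)`
#' independent of `x`, for the three mean functions used in the comparative
#' study of association measures:
#' `linear` (`m(x) = x`), `quadratic` (`m(x) = 1 - 4(x - 1/2)^2`), and
#' `periodic_abs_sine` (`m(x) = |sin(2 pi freq x)|`, with `freq` full periods
#' on the unit interval).
#'
#' @param n Sample size.
#' @param kind One of `"linear"`, `"quadratic"`, `"periodic_abs_sine"`.
#' @param sigma Noise standard deviation (>= 0).
#' @param freq Number of periods; used only by `kind = "periodic_abs_sine"`.
#' @param seed Optional integer seed.
#' @return A [paired_sample()].
#' @export
gen_noisy_function <- function(n, kind = c("linear", "quadratic", "periodic_abs_sine"),
                               sigma = 0, freq = 1, seed = NULL) {
  n <- check_count(n, 2L)
  kind <- match.arg(kind)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (freq < 0) stop("`freq` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n)
  m <- switch(kind,
    linear = x,
    quadratic = 1 - 4 * (x - 0.5)^2,
    periodic_abs_sine = abs(sin(2 * pi * freq * x))
  )
  y <- m + if (sigma > 0) stats::rnorm(n, sd = sigma) else 0
  paired_sample(x, y)
}

#' Mixture of rotated unit squares (or diagonal bands)
#'
#' Equal-weight mixture of `K` unit squares centered at `(2i, 0)`,
#' `i = 1..K`, each rotated by the angle `theta`. With `b < 1` each square is
#' restricted to the diagonal band between the lines joining
#' `(-1/2, -1/2 + b)`--`(1/2 - b, 1/2)` and `(-1/2 + b, -1/2)`--`(1/2, 1/2 - b)`,
#' so that as `b` shrinks each component concentrates on a line segment and
#' within-component association rises toward 1, while the components stay
#' pairwise disjoint (separation at least 1 between square hulls). Band points
#' are drawn by rejection sampling from the unit square.
#'
#' @param n Sample size.
#' @param K Number of components (>= 1).
#' @param theta Rotation angle in `(0, pi/4]`.
#' @param b Band thickness in `(0, 1]`; `b = 1` keeps the full square.
#' @param seed Optional integer seed.
#' @return A [labeled_sample()] with labels `1..K`.
#' @export
gen_rotated_squares <- function(n, K = 1L, theta = pi / 4, b = 1, seed = NULL) {
  n <- check_count(n, 2L)
  K <- check_count(K, 1L)
  if (theta <= 0 || theta > pi / 4) stop("`theta` must lie in (0, pi/4]", call. = FALSE)
  if (b <= 0 || b > 1) stop("`b` must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lab <- sample.int(K, n, replace = TRUE)
  a <- matrix(stats::runif(2L * n, -0.5, 0.5), ncol = 2L)
  if (b < 1) {
    # keep |x - y| <= b: the diagonal band between the two stated lines;
    # b = 1 is the whole square, b -> 0 collapses onto the diagonal
    bad <- abs(a[, 1L] - a[, 2L]) > b
    while (any(bad)) {
      a[bad, ] <- stats::runif(2L * sum(bad), -0.5, 0.5)
      bad <- abs(a[, 1L] - a[, 2L]) > b
    }
  }
  a[, 1L] <- a[, 1L] + 2 * lab
  u <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  z <- a %*% t(u)
  labeled_sample(z[, 1L], z[, 2L], lab)
}

#' Uniform sample on the unit circle
#'
#' Angles uniform on `[0, 2*pi)`; `x = cos`, `y = sin`, so `x^2 + y^2 = 1`
#' holds to machine precision. On this implicit relationship Chatterjee's
#' correlation converges to 1/4 in both directions, the canonical example of a
#' perfect non-functional dependence that rank-functional measures undervalue.
#'
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return A [paired_sample()].
#' @export
gen_circle <- function(n, seed = NULL) {
  n <- check_count(n, 2L)
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  paired_sample(cos(th), sin(th))
}

#' Two well-separated uniform blocks
#'
#' Half-half mixture of `Unif([0,1]^2)` and `Unif([2,3]^2)`. Within each block
#' the coordinates are independent, so the cluster-based association is 0 even
#' though X and Y are globally dependent through block membership; the blocks
#' are separated by Euclidean distance `sqrt(2)`.
#'
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return A [labeled_sample()] with labels 1 and 2.
#' @export
gen_two_blocks <- function(n, seed = NULL) {
  n <- check_count(n, 2L)
  if (!is.null(seed)) set.seed(seed)
  lab <- 1L + stats::rbinom(n, 1L, 0.5)
  x <- stats::runif(n) + 2 * (lab == 2L)
  y <- stats::runif(n) + 2 * (lab == 2L)
  labeled_sample(x, y, lab)
}

#' Add an ambient uniform noise component
#'
#' Contaminates a labeled sample with weight-`(1 - sum(alpha))` ambient noise,
#' realized as points uniform on an inflated bounding box of the existing
#' sample. Noise points get `true_label` 0. The low-dimensional components
#' plus ambient noise mimic the low-dimensional-large-noise sampling model
#' that the clustering guarantees are stated under.
#'
#' @param sample A [labeled_sample()].
#' @param noise_frac Fraction of the returned sample that is ambient noise,
#'   in `[0, 1)`; default 0 (no noise).
#' @param expand Multiplicative box expansion factor (default 1.5).
#' @param seed Optional integer seed.
#' @return A [labeled_sample()] of size `ceiling(n / (1 - noise_frac))`.
#' @export
add_ambient_noise <- function(sample, noise_frac = 0, expand = 1.5, seed = NULL) {
  stopifnot(inherits(sample, "labeled_sample"))
  if (noise_frac < 0 || noise_frac >= 1) stop("`noise_frac` must lie in [0, 1)", call. = FALSE)
  if (noise_frac == 0) return(sample)
  if (!is.null(seed)) set.seed(seed)
  pts <- joint_points(sample)
  m <- ceiling(sample$n * noise_frac / (1 - noise_frac))
  ctr <- colMeans(pts)
  half <- (apply(pts, 2L, max) - apply(pts, 2L, min)) / 2 * expand
  noise <- sapply(seq_along(ctr), function(j) stats::runif(m, ctr[j] - half[j], ctr[j] + half[j]))
  noise <- matrix(noise, nrow = m)
  p <- ncol(sample$x)
  labeled_sample(
    rbind(sample$x, noise[, seq_len(p), drop = FALSE]),
    rbind(sample$y, noise[, -seq_len(p), drop = FALSE]),
    c(sample$true_labels, rep(0L, m))
  )
}

check_count <- function(n, min) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < min) {
    stop(sprintf("expected an integer count >= %d", min), call. = FALSE)
  }
  as.integer(n)
}
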