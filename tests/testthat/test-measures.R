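test_that("chatterjee reproduces hand-computed values and handles degenerate input", {
  expect_equal(chatterjee(1:5, 1:5)$value, 0.5)            # 1 - 3/(n+1)
  expect_equal(chatterjee(1:5, c(1, 5, 2, 4, 3))$value, -0.25)
  expect_warning(out <- chatterjee(1:10, rep(1, 10)), "constant")
  expect_equal(out$value, 0)
  # tie-aware form agrees with the tie-free formula on tie-free data
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  r <- rank(y[order(x)])
  expect_equal(chatterjee(x, y)$value, 1 - 3 * sum(abs(diff(r))) / (50^2 - 1))
})

test_that("chatterjee is asymmetric with symmetrization by max", {
  set.seed(2)
  x <- runif(500); y <- x^3 + rnorm(500, sd = 0.05)
  expect_equal(chatterjee_sym(x, y)$value,
               max(chatterjee(x, y)$value, chatterjee(y, x)$value))
  expect_equal(chatterjee_sym(x, x)$value, chatterjee(x, x)$value)
  # monotone deterministic relation: both directions near 1
  yy <- exp(x)
  expect_gt(chatterjee(x, yy)$value, 0.95)
  expect_gt(chatterjee(yy, x)$value, 0.95)
})

test_that("chatterjee null fluctuations follow the sqrt(2/5n) asymptotics", {
  set.seed(3)
  vals <- replicate(20, {
    x <- rnorm(5000); y <- rnorm(5000)
    chatterjee_sym(x, y)$value
  })
  expect_true(all(abs(vals) <= 4 * sqrt(0.4 / 5000)))
})

test_that("alternating-y constructions give negative sample values, bounded by -1/2", {
  # strictly alternating signs with growing magnitude: negative both ways
  m <- 150
  x <- (-m):m
  y <- (abs(x) + 1) * ifelse(x %% 2 == 0, 1, -1)
  cxy <- chatterjee(x, y, seed = 1)$value
  cyx <- chatterjee(y, x, seed = 1)$value
  expect_lt(cxy, 0); expect_gte(cxy, -0.5)
  expect_lt(cyx, 0); expect_gte(cyx, -0.5)
  # the mod-3 deterministic family: perfect dependence yet estimates near 0
  y3 <- (abs(x) + 1) * (2 * (((x %% 3) + 3) %% 3 == 1) - 1)
  expect_lt(abs(chatterjee(x, y3, seed = 1)$value), 0.05)
  expect_lt(chatterjee(y3, x, seed = 1)$value, 0.05)
})

test_that("dcor is 1 on affine isometries, small under independence, 0 when degenerate", {
  set.seed(4)
  x <- rnorm(100)
  expect_equal(dcor(x, x)$value, 1)
  expect_equal(dcor(x, -3 * x + 2)$value, 1)
  u <- runif(5000); v <- runif(5000)
  expect_lte(dcor(u, v)$value, 0.05)
  expect_warning(z <- dcor(x, rep(1, 100)), "degenerate")
  expect_equal(z$value, 0)
  # multivariate input
  X <- matrix(rnorm(200), ncol = 2)
  expect_equal(dcor(X, X %*% matrix(c(0, -1, 1, 0), 2, 2))$value, 1)
})

test_that("copula coefficient vanishes under independence and detects monotone maps", {
  set.seed(5)
  u <- runif(2000)
  expect_lt(copula_corr(u, runif(2000))$value, 0.12)
  expect_gt(copula_corr(u, u)$value, 0.9)
  expect_gt(copula_corr(u, -u^3)$value, 0.9)   # strictly decreasing map
})

test_that("pearson and spearman endpoints behave", {
  x <- 1:20
  expect_equal(pearson_corr(x, x)$value, 1)
  expect_equal(pearson_corr(x, -x)$value, -1)
  expect_equal(spearman_corr(x, exp(x / 20))$value, 1)
  q <- gen_noisy_function(5000, "quadratic", sigma = 0, seed = 6)
  expect_lt(abs(pearson_corr(q$x[, 1], q$y[, 1])$value), 0.05)
  expect_gt(chatterjee(q$x[, 1], q$y[, 1])$value, 0.95)
})

test_that("estimator outputs respect their ranges (B1)", {
  set.seed(7)
  cases <- list(
    indep = list(x = rnorm(300), y = rnorm(300)),
    linear = list(x = runif(300), y = runif(300) * 0.1 + (1:300) / 300),
    quad = {
      x <- runif(300)
      list(x = x, y = 1 - 4 * (x - 0.5)^2 + rnorm(300, sd = 0.3))
    },
    heavy = list(x = rcauchy(300), y = rcauchy(300))
  )
  for (cs in cases) {
    expect_true(dcor(cs$x, cs$y)$value >= 0 && dcor(cs$x, cs$y)$value <= 1)
    r <- ace_maximal(cs$x, cs$y)$rho
    expect_true(r >= 0 && r <= 1 + 1e-12)
    m <- mic(cs$x, cs$y)$value
    expect_true(m >= 0 && m <= 1)
    co <- copula_corr(cs$x, cs$y)$value
    expect_true(co >= 0 && co <= 1)
    ch <- chatterjee(cs$x, cs$y)$value
    expect_true(ch >= -0.5 && ch <= 1)
  }
})

test_that("rank-based measures are invariant to strictly increasing transforms (B4)", {
  set.seed(8)
  x <- rnorm(400); y <- x^2 + rnorm(400, sd = 0.3)
  tx <- function(v) exp(v)          # strictly increasing
  ty <- function(v) atan(v) + v^3   # strictly increasing
  expect_equal(chatterjee(tx(x), ty(y), seed = 9)$value,
               chatterjee(x, y, seed = 9)$value, tolerance = 1e-12)
  expect_equal(spearman_corr(tx(x), ty(y))$value, spearman_corr(x, y)$value,
               tolerance = 1e-12)
  expect_equal(copula_corr(tx(x), ty(y))$value, copula_corr(x, y)$value,
               tolerance = 1e-12)
  set.seed(10); m1 <- mic(x, y)$value
  set.seed(10); m2 <- mic(tx(x), ty(y))$value
  expect_equal(m1, m2, tolerance = 1e-12)
  # negative control: dcor depends on the marginal geometry
  expect_gt(abs(dcor(tx(x), y)$value - dcor(x, y)$value), 1e-3)
})

test_that("null 95th percentiles at n = 1000 stay below 0.15 for the [0,1] measures", {
  set.seed(11)
  nulls <- sapply(seq_len(200), function(i) {
    x <- runif(1000); y <- runif(1000)
    c(dcor = dcor(x, y)$value,
      maximal = ace_maximal(x, y)$rho,
      mic = mic(x, y)$value,
      copula = copula_corr(x, y)$value)
  })
  q95 <- apply(nulls, 1, stats::quantile, probs = 0.95)
  expect_true(all(q95 < 0.15), info = paste(names(q95), round(q95, 3), collapse = ", "))
})

test_that("noise-robustness and periodicity orderings across measures hold", {
  # monotone signal with heavy noise: the smooth measures beat chatterjee
  lin <- gen_noisy_function(5000, "linear", sigma = 1, seed = 12)
  x <- lin$x[, 1]; y <- lin$y[, 1]
  ch <- chatterjee_sym(x, y)$value
  expect_gt(abs(spearman_corr(x, y)$value), ch)
  expect_gt(dcor(x, y)$value, ch)
  expect_gt(ace_maximal(x, y)$rho, ch)
  expect_gt(copula_corr(x, y)$value, ch)

  # same for the quadratic signal (spearman excluded: it is ~0 by symmetry)
  quad <- gen_noisy_function(5000, "quadratic", sigma = 1, seed = 13)
  xq <- quad$x[, 1]; yq <- quad$y[, 1]
  chq <- chatterjee_sym(xq, yq)$value
  expect_gt(dcor(xq, yq)$value, chq)
  expect_gt(ace_maximal(xq, yq)$rho, chq)
  expect_gt(copula_corr(xq, yq)$value, chq)

  # 16 periods, light noise: chatterjee and MIC dominate the others
  per <- gen_noisy_function(5000, "periodic_abs_sine", sigma = 0.1,
                            freq = 16, seed = 14)
  xp <- per$x[, 1]; yp <- per$y[, 1]
  others <- c(dcor(xp, yp)$value, ace_maximal(xp, yp)$rho,
              copula_corr(xp, yp)$value)
  expect_true(all(chatterjee(xp, yp)$value > others))
  expect_true(all(mic(xp, yp)$value > others))
})

test_that("association() dispatches and symmetrizes consistently", {
  set.seed(15)
  x <- runif(100); y <- x + rnorm(100, sd = 0.1)
  for (m in c("pearson", "spearman", "chatterjee", "dcor", "mic", "copula")) {
    out <- association(x, y, m)
    expect_s3_class(out, "assoc_value")
    expect_identical(out$measure, m)
  }
  a <- association(x, y, "chatterjee", sym = TRUE, params = list(seed = 1))
  expect_identical(a$direction, "sym")
  expect_equal(a$value, chatterjee_sym(x, y, seed = 1)$value)
})
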