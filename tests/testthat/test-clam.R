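test_that("weights sum to 1 and the overall value is their convex combination", {
  s <- gen_gaussian_mixture(400, 0.3, pi / 4, seed = 1)
  cl <- ng_clusters(s, r = 0.5)
  res <- suppressWarnings(clam_estimate(s, "chatterjee", cl, sym = TRUE))
  expect_equal(sum(res$summaries$alpha), 1)
  expect_equal(res$overall, sum(res$summaries$alpha * res$summaries$rho),
               tolerance = 1e-12)
  expect_gte(res$overall, min(res$summaries$rho) - 1e-12)
  expect_lte(res$overall, max(res$summaries$rho) + 1e-12)
  expect_equal(res$n_used + res$n_noise, s$n)
})

test_that("a single merged cluster reproduces the plain estimate exactly", {
  s <- gen_gaussian_mixture(300, 0.3, pi / 6, seed = 2)
  plain <- ace_maximal(s$x[, 1], s$y[, 1])$rho
  res <- clam_pipeline(s, "maximal", "ng", r = 50)
  expect_identical(res$overall, plain)
  expect_equal(res$summaries$alpha, 1)
  # spectral route with huge sigma merges too
  res2 <- clam_pipeline(s, "maximal", "sc", sigma = 100, distance = "llpd")
  expect_identical(res2$overall, plain)
})

test_that("two uniform blocks: cluster-based value near 0, plain values large", {
  b <- gen_two_blocks(2000, seed = 3)
  x <- b$x[, 1]; y <- b$y[, 1]
  cl <- ng_clusters(b, r = 0.5)
  for (m in c("chatterjee", "maximal", "dcor")) {
    sym <- m == "chatterjee"
    res <- suppressWarnings(clam_estimate(b, m, cl, sym = sym))
    plain <- suppressWarnings(association(x, y, m, sym = sym)$value)
    expect_lte(res$overall, 0.1)
    if (m == "chatterjee") {
      # population value of xi here is exactly 1/2: within blocks the
      # coordinates are independent, so Var(E[1{Y>=t}|X]) integrates to 1/12
      # against the mixture law while Var(1{Y>=t}) integrates to 1/6
      expect_gt(plain, 0.5 - 3 * sqrt(0.4 / 2000))
    } else {
      expect_gt(plain, 0.5)
    }
  }
})

test_that("the maximal-correlation combination equals the score inner products", {
  s <- gen_gaussian_mixture(300, 0.3, pi / 6, seed = 4)
  cl <- ng_clusters(s, r = 0.5)
  res <- suppressWarnings(clam_estimate(s, "maximal", cl))
  manual <- sum(vapply(seq_len(nrow(res$summaries)), function(i) {
    k <- res$summaries$cluster[i]
    idx <- cl$labels == k
    fit <- ace_maximal(s$x[idx, 1], s$y[idx, 1])
    res$summaries$alpha[i] * mean(fit$f_scores * fit$g_scores)
  }, 0))
  expect_equal(res$overall, manual, tolerance = 1e-10)
})

test_that("cluster summaries report sizes, weights and centroids correctly", {
  b <- gen_two_blocks(4000, seed = 5)
  cl <- ng_clusters(b, r = 0.5)
  ws <- weighted_summaries(cl, b)
  expect_equal(nrow(ws), 2L)
  expect_equal(sum(ws$alpha), 1)
  expect_lt(max(abs(ws$alpha - 0.5)), 3 * sqrt(0.25 / 4000) + 0.02)
  cents <- ws[, c("x1", "y1")]
  lo <- which.min(cents$x1); hi <- which.max(cents$x1)
  expect_lt(max(abs(unlist(cents[lo, ]) - 0.5)), 0.05)
  expect_lt(max(abs(unlist(cents[hi, ]) - 2.5)), 0.05)

  # single cluster: weight exactly 1
  one <- ng_clusters(joint_points(b), r = 50)
  expect_equal(weighted_summaries(one, b)$alpha, 1)

  # minority-cluster centroid near the minority center (ground-truth
  # partition: at this density the Gaussian tails bridge any radius graph)
  s <- gen_gaussian_mixture(10000, 0.1, 0, seed = 6)
  cls <- clamcor:::new_clusters(s$true_labels, "NG", params = list())
  wss <- weighted_summaries(cls, s)
  small <- wss[which.min(wss$alpha), ]
  expect_lt(max(abs(unlist(small[, c("x1", "y1")]) - c(6, 0))), 0.1)
})

test_that("the pipeline is deterministic and ng/sc agree on well-separated blocks", {
  b <- gen_two_blocks(600, seed = 7)
  r1 <- clam_pipeline(b, "chatterjee", "ng", r = 0.5, sym = TRUE,
                      measure_params = list(seed = 3))
  r2 <- clam_pipeline(b, "chatterjee", "ng", r = 0.5, sym = TRUE,
                      measure_params = list(seed = 3))
  expect_identical(serialize_result_for_test(r1), serialize_result_for_test(r2))
  rsc <- clam_pipeline(b, "chatterjee", "sc", sigma = 1, distance = "g",
                       g = g_function("power", 10), sym = TRUE,
                       measure_params = list(seed = 3))
  expect_lt(abs(r1$overall - rsc$overall), 0.02)
})

test_that("degenerate clusters degrade to rho = 0 with a warning instead of aborting", {
  # two tight groups, one with constant y: the measure degenerates there
  set.seed(8)
  x <- c(rnorm(50, sd = 0.05), rnorm(50, 10, sd = 0.05))
  y <- c(rnorm(50, sd = 0.05), rep(2, 50))
  ps <- paired_sample(x, y)
  cl <- ng_clusters(ps, r = 0.5, s = 3)
  expect_equal(cl$K, 2L)
  expect_warning(res <- clam_estimate(ps, "chatterjee", cl), "degener")
  expect_gte(res$n_warnings, 1L)
  expect_true(any(res$summaries$rho == 0))
  expect_error(
    clam_estimate(ps, "chatterjee",
                  suppressWarnings(ng_clusters(ps, r = 1e-9, s = 3))),
    "no clusters"
  )
})

test_that("rotated-square mixtures separate plain and cluster-based regimes", {
  # growing K at full squares: the plain value climbs, the cluster-based
  # value stays at its single-component level
  base <- NULL
  for (K in 1:3) {
    s <- gen_rotated_squares(900, K = K, theta = pi / 4, b = 1, seed = 9)
    plain <- dcor(s$x[, 1], s$y[, 1])$value
    res <- suppressWarnings(clam_pipeline(s, "dcor", "ng", r = 0.3))
    if (K == 1) {
      base <- res$overall
      expect_equal(plain, res$overall, tolerance = 1e-12)
    } else {
      expect_gt(plain, 0.5)
      expect_lt(abs(res$overall - base), 0.05)
    }
  }
  # shrinking band: within-component dependence rises toward 1
  vals <- sapply(c(1, 0.5, 0.2, 0.05), function(b) {
    s <- gen_rotated_squares(900, K = 2, theta = pi / 8, b = b, seed = 10)
    suppressWarnings(clam_pipeline(s, "dcor", "ng", r = 0.3))$overall
  })
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[4], 0.95)
})
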