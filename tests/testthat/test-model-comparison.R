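# Second-order analysis: space correlations, ranking, hierarchical
# regression, bootstrap model comparison.

test_that("space correlation handles identity, independence, and missing cells", {
  v <- rnorm(200)
  sc <- space_correlation(v, v)
  expect_equal(sc$r, 1, tolerance = 1e-12)
  expect_equal(sc$n_complete, 200)

  n_small <- sum(vapply(1:20, function(s) {
    ab <- scenespace:::with_seed(s, list(a = rnorm(4950), b = rnorm(4950)))
    abs(space_correlation(ab$a, ab$b)$r) < 0.05
  }, logical(1)))
  expect_gte(n_small, 19)

  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  a[c(3, 9)] <- NA; b[c(9, 17)] <- NA
  ok <- !(seq_len(50) %in% c(3, 9, 17))
  sc2 <- space_correlation(a, b)
  expect_equal(sc2$r, pearson_oracle(a[ok], b[ok]), tolerance = 1e-12)
  expect_equal(sc2$n_complete, 47)
  expect_equal(sc2$p, stats::cor.test(a[ok], b[ok])$p.value)

  expect_error(space_correlation(c(1, 2, NA), c(NA, 2, 3)), "fewer than 3")
  expect_error(space_correlation(rnorm(5), rnorm(6)), "equal length")
})

test_that("correlation tables are symmetric with correction-dependent flags", {
  spaces <- scenespace:::with_seed(2, list(a = rnorm(300),
                                           b = rnorm(300),
                                           c = rnorm(300)))
  spaces$b <- spaces$b + 0.8 * spaces$a
  ct <- correlation_table(spaces, correction = "bonferroni_pairs")
  expect_equal(ct$r, t(ct$r))
  expect_equal(diag(ct$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(ct$alpha_cell, 0.05 / 300)
  expect_equal(sum(!is.na(ct$p[upper.tri(ct$p)])), 3)

  # flags equal brute-force thresholding
  expect_equal(ct$significant[upper.tri(ct$r)],
               ct$p[upper.tri(ct$p)] < 0.05 / 300)

  ct39 <- correlation_table(spaces, correction = "bonferroni_m",
                            m_family = 39)
  expect_equal(ct39$alpha_cell, 0.05 / 39)
  expect_equal(ct39$r, ct$r)

  # duplicated space: off-diagonal unit correlation
  ct2 <- correlation_table(list(x = spaces$a, y = spaces$a))
  expect_equal(ct2$r[1, 2], 1, tolerance = 1e-12)

  # permutation equivariance in the labels
  perm <- correlation_table(spaces[c(3, 1, 2)])
  expect_equal(perm$r[c("a", "b", "c"), c("a", "b", "c")],
               ct$r[c("a", "b", "c"), c("a", "b", "c")])
})

test_that("model ranking orders by correlation with deterministic tie-breaks", {
  target <- rnorm(100)
  expect_equal(rank_models(target, list(only = rnorm(100)))$label, "only")

  models <- scenespace:::with_seed(4, list(
    far = rnorm(100), x = target + rnorm(100, sd = 0.1), mid = 0.3 * target + rnorm(100)))
  rk <- rank_models(target, models)
  expect_equal(rk$label[1], "x")
  expect_equal(rk$r, sort(rk$r, decreasing = TRUE))
  expect_equal(nrow(rank_models(target, models, top_k = 2)), 2)
})

test_that("hierarchical regression matches independent nested fits and the single-predictor identity", {
  set.seed(7)
  n <- 120
  y <- rnorm(n)
  b1 <- matrix(rnorm(2 * n), n, 2)
  b2 <- matrix(rnorm(3 * n), n, 3)
  b3 <- matrix(0.4 * y + rnorm(3 * n), n, 3)
  hf <- hierarchical_regression(y, list(low = b1, mid = b2, high = b3))

  # oracle: R2 of each nested model from two independent lm() fits
  r2a <- summary(stats::lm(y ~ b1))$r.squared
  r2b <- summary(stats::lm(y ~ b1 + b2))$r.squared
  r2c <- summary(stats::lm(y ~ b1 + b2 + b3))$r.squared
  expect_equal(hf$delta_R2, c(r2a, r2b - r2a, r2c - r2b), tolerance = 1e-10)
  expect_equal(hf$cumulative_R, sqrt(c(r2a, r2b, r2c)), tolerance = 1e-10)
  expect_true(all(diff(hf$cumulative_R) >= -1e-12))
  expect_equal(sum(hf$delta_R), hf$cumulative_R[3], tolerance = 1e-12)
  expect_true(hf$significant_uncorrected[3])

  # single block, single predictor: R equals |r|
  x1 <- 0.5 * y + rnorm(n)
  h1 <- hierarchical_regression(y, list(one = matrix(x1)))
  expect_equal(h1$cumulative_R[1], abs(pearson_oracle(y, x1)),
               tolerance = 1e-12)

  # target exactly linear in block 1: R = 1 immediately, later increments 0
  yl <- b1 %*% c(1, -2)
  hl <- hierarchical_regression(as.numeric(yl), list(low = b1, mid = b2))
  expect_equal(hl$cumulative_R[1], 1, tolerance = 1e-10)
  expect_equal(hl$delta_R[2], 0, tolerance = 1e-8)

  expect_error(hierarchical_regression(y, list(a = b1, dup = b1)),
               "rank-deficient")
  expect_error(hierarchical_regression(rnorm(4),
                                       list(a = matrix(rnorm(20), 4, 5))),
               "below the observation count")
})

test_that("bootstrap model comparison is reproducible with sane interval behavior", {
  z <- scenespace:::with_seed(10, {
    t <- rnorm(400); a <- 0.5 * t + rnorm(400); list(t = t, a = a)
  })
  # identical models: zero difference, CI straddles 0
  br <- bootstrap_model_difference(z$t, z$a, z$a, n_iter = 500, seed = 3)
  expect_equal(br$estimate, 0)
  expect_true(br$ci[1] <= 0 && br$ci[2] >= 0)
  expect_false(br$significant)

  b <- scenespace:::with_seed(11, 0.1 * z$t + rnorm(400))
  br2 <- bootstrap_model_difference(z$t, z$a, b, n_iter = 500, seed = 5)
  expect_equal(br2$estimate,
               stats::cor(z$t, z$a)^2 - stats::cor(z$t, b)^2,
               tolerance = 1e-12)
  expect_true(br2$ci[1] <= br2$estimate && br2$estimate <= br2$ci[2])
  expect_identical(br2$replicates,
                   bootstrap_model_difference(z$t, z$a, b, n_iter = 500,
                                              seed = 5)$replicates)
  # Bonferroni widening across a declared family
  br3 <- bootstrap_model_difference(z$t, z$a, b, n_iter = 500, seed = 5,
                                    family = 10)
  expect_gte(diff(br3$ci), diff(br2$ci))
  expect_equal(br3$level_used, 1 - 0.05 / 10)

  expect_error(bootstrap_model_difference(z$t, z$a, b, n_iter = 10), "n_iter")
})

test_that("end-to-end mixture recovery ranks the generating model first with the largest increment", {
  spaces <- orthogonal_model_spaces(30, k = 3, seed = 20)
  mx <- ground_truth_mixture(spaces, weights = c(0.6, 0.3, 0.1),
                             noise_sd = 1, seed = 21)
  tp <- gen_voxel_patterns(mx, n_voxels = 120)
  v <- fisher_space(pairwise_similarity(build_scene_patterns(tp)$patterns))
  rk <- rank_models(v, list(m1 = spaces[[1]], m2 = spaces[[2]],
                            m3 = spaces[[3]]))
  expect_equal(rk$label[1], "m1")

  # weakest-first entry order: the dominant model still adds the most R
  hf <- hierarchical_regression(v, list(m3 = matrix(spaces[[3]]),
                                        m2 = matrix(spaces[[2]]),
                                        m1 = matrix(spaces[[1]])))
  expect_equal(hf$block[which.max(hf$delta_R)], "m1")
})
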