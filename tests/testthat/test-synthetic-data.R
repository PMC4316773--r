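# Synthetic generators: determinism, planted structure, and recovery.

test_that("stimulus sets have the declared category layout and are seed-deterministic", {
  st <- gen_scene_images(50, 2, 64, seed = 1)
  expect_length(st$images, 100)
  expect_equal(unname(table(st$category_of)), rep(2L, 50),
               ignore_attr = TRUE)
  expect_equal(length(unique(st$category_of)), 50)

  a <- gen_scene_images(2, 1, 32, seed = 77)
  b <- gen_scene_images(2, 1, 32, seed = 77)
  expect_identical(a$images, b$images)
  expect_false(identical(a$images, gen_scene_images(2, 1, 32, seed = 78)$images))

  expect_error(gen_scene_images(0, 2, 64), "n_categories")
  expect_error(gen_scene_images(5, 2, 16), "size")
})

test_that("within-category pairs are more GIST-similar than between-category pairs", {
  st <- gen_scene_images(5, 4, 64, seed = 3)
  G <- t(vapply(st$images, gist_descriptor, numeric(512)))
  S <- pairwise_similarity(G)
  same <- outer(st$category_of, st$category_of, `==`)
  ut <- upper.tri(S)
  expect_gt(mean(S[same & ut]), mean(S[!same & ut]))
})

test_that("attribute score tables carry a tunable category effect", {
  st <- gen_scene_images(6, 3, 32, seed = 2)
  at <- gen_attribute_scores(st, 84, seed = 5)
  expect_equal(ncol(at$scores), 84)
  expect_equal(nrow(at$scores), 18)

  flat <- gen_attribute_scores(st, 5, category_effect = 0, noise_sd = 0,
                               seed = 1)
  expect_true(all(apply(flat$scores, 2, function(x) max(x) - min(x)) == 0))

  strong <- gen_attribute_scores(st, 40, category_effect = 5,
                                 noise_sd = 0.05, seed = 4)
  Sa <- pairwise_similarity(strong$scores)
  cat01 <- outer(st$category_of, st$category_of, `==`) * 1
  ut <- upper.tri(Sa)
  expect_gt(cor(Sa[ut], cat01[ut]), 0.9)

  expect_error(gen_attribute_scores(st, 5, noise_sd = -1), "noise_sd")
})

test_that("noiseless voxel patterns reproduce a single active model space exactly", {
  spaces <- orthogonal_model_spaces(12, k = 2, seed = 4)
  mx <- ground_truth_mixture(spaces, weights = c(1, 0), noise_sd = 0, seed = 6)
  tp <- gen_voxel_patterns(mx, n_voxels = 40, n_repetitions = 6)
  expect_equal(dim(tp$responses)[2], 6)
  pm <- build_scene_patterns(tp)
  v <- upper_triangle(pairwise_similarity(pm$patterns))
  expect_gt(cor(as.numeric(v), spaces[[1]]), 0.99)
  expect_equal(as.numeric(v), spaces[[1]], tolerance = 1e-10)

  tp2 <- gen_voxel_patterns(mx, n_voxels = 40, n_repetitions = 6)
  expect_identical(tp$responses, tp2$responses)
})

test_that("model-ranking fidelity degrades monotonically with voxel noise", {
  spaces <- orthogonal_model_spaces(20, k = 3, seed = 8)
  true_rank <- c(3, 2, 1)                 # by descending weight
  mean_rho <- vapply(c(0.1, 1, 10), function(nsd) {
    rhos <- vapply(1:12, function(s) {
      mx <- ground_truth_mixture(spaces, weights = c(0.5, 0.3, 0.2),
                                 noise_sd = nsd, seed = 100 * s)
      tp <- gen_voxel_patterns(mx, n_voxels = 60)
      v <- fisher_space(pairwise_similarity(build_scene_patterns(tp)$patterns))
      rs <- vapply(spaces, function(m) space_correlation(v, m)$r, numeric(1))
      cor(rank(rs), true_rank, method = "spearman")
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_true(all(diff(mean_rho) <= 0))
  expect_gt(mean_rho[1], mean_rho[3])
})

test_that("unrealizable similarity mixtures are reported, not silently clipped", {
  n <- 4
  v <- rep(-0.9, n * (n - 1) / 2)        # mutually anti-correlated: not PSD
  mx <- ground_truth_mixture(list(v), 1, noise_sd = 0, seed = 1)
  expect_warning(tp <- gen_voxel_patterns(mx, n_voxels = 10),
                 "positive semidefinite")
  expect_true(attr(tp, "psd_adjusted"))
  S <- attr(tp, "target_similarity")
  expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-10)
})

test_that("rating tables cover all pairs, embed one catch per HIT, and skew right", {
  rt <- gen_ratings(rnorm(4950), n_obs_per_pair = 20, n_bad_raters = 0,
                    seed = 2)
  non_catch <- rt[!rt$is_catch, ]
  keys <- paste(pmin(non_catch$scene_a, non_catch$scene_b),
                pmax(non_catch$scene_a, non_catch$scene_b))
  expect_equal(length(unique(keys)), 4950)
  expect_equal(unname(table(keys))[1], 20, ignore_attr = TRUE)

  catch_per_hit <- tapply(rt$is_catch, paste(rt$rater, rt$hit), sum)
  expect_true(all(catch_per_hit == 1))
  expect_true(all(tapply(rt$is_catch, paste(rt$rater, rt$hit), length) == 11))

  expect_gt(scenespace:::sample_skewness(non_catch$response), 1)

  rt2 <- gen_ratings(rnorm(45), 4, n_bad_raters = 0, seed = 3)
  bm <- behavioral_matrix(rt2, 10)
  expect_length(attr(bm, "raters_dropped"), 0)

  expect_identical(gen_ratings(rnorm(45), 2, 1, seed = 5),
                   gen_ratings(rnorm(45), 2, 1, seed = 5))
})

test_that("geometric-class maps are proper per-pixel probability distributions", {
  st <- gen_scene_images(3, 2, 32, seed = 6)
  maps <- gen_geom_maps(st, map_size = 16, seed = 2)
  expect_length(maps, 6)
  expect_named(maps[[1]], c("gnd", "vrt", "por", "sky"))
  tot <- Reduce(`+`, maps[[1]])
  expect_equal(tot, matrix(1, 16, 16), tolerance = 1e-12)
  expect_true(all(vapply(maps[[1]], function(m) all(m >= 0 & m <= 1),
                         logical(1))))
})
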