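# First-order similarity spaces, Fisher transform, vectorization, split-half.

test_that("pairwise similarity matches a per-pair Pearson oracle and handles degenerate rows", {
  f <- matrix(rnorm(100), 10, 10)
  S <- pairwise_similarity(f)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(S[i, j], pearson_oracle(f[i, ], f[j, ]), tolerance = 1e-12)
  }
  expect_equal(S[2, 2], 1)

  two <- rbind(f[1, ], f[1, ])
  expect_equal(pairwise_similarity(two)[1, 2], 1)
  expect_equal(pairwise_similarity(rbind(f[1, ], -f[1, ]))[1, 2], -1)

  degen <- rbind(f[1:3, ], rep(2, 10))
  expect_warning(Sd <- pairwise_similarity(degen), "zero-variance")
  expect_true(all(is.na(Sd[4, -4])))
  expect_equal(Sd[4, 4], 1)
})

test_that("pairwise similarity is invariant to positive per-scene affine maps", {
  f <- matrix(rnorm(80), 8, 10)
  a <- runif(8, 0.5, 3); b <- rnorm(8)
  g <- f * a + b
  expect_equal(as.numeric(pairwise_similarity(g)),
               as.numeric(pairwise_similarity(f)), tolerance = 1e-10)
})

test_that("Fisher transform is the odd, invertible atanh with clamping at unity", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("upper-triangle vectorization is row-major and round-trips", {
  m <- matrix(c(1, .1, .2,
                .1, 1, .3,
                .2, .3, 1), 3, 3)
  v <- upper_triangle(m)
  expect_equal(as.numeric(v), c(.1, .2, .3))      # (1,2), (1,3), (2,3)

  big <- pairwise_similarity(matrix(rnorm(100 * 20), 100, 20))
  vb <- upper_triangle(big)
  expect_length(vb, 4950)
  expect_equal(reconstruct_similarity(vb), unclass(big),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_length(upper_triangle(diag(2)), 1)
  asym <- m; asym[1, 2] <- 0.9
  expect_error(upper_triangle(asym), "asymmetric")

  # missing cells survive the round trip
  mm <- m; mm[1, 3] <- mm[3, 1] <- NA
  expect_equal(as.numeric(upper_triangle(mm)), c(.1, NA, .3))
})

test_that("split-half reliability is 1 for identical halves and near 0 for pure noise", {
  spaces <- orthogonal_model_spaces(10, k = 1, seed = 2)
  mx <- ground_truth_mixture(spaces, 1, noise_sd = 0, seed = 4)
  tp <- gen_voxel_patterns(mx, n_voxels = 30, n_repetitions = 4)
  sh <- split_half(tp, by = "session")
  expect_equal(sh$reliability, 1, tolerance = 1e-9)
  expect_equal(stats::cor(sh$half1, sh$half2), sh$reliability)

  sh2 <- split_half(tp, by = "odd_even")
  expect_equal(sh2$reliability, 1, tolerance = 1e-9)

  n_ok <- sum(vapply(1:20, function(s) {
    noise <- scenespace:::with_seed(s,
      array(rnorm(50 * 2 * 2 * 40), c(50, 2, 2, 40)))
    tpn <- trial_pattern_array(noise, spacing = 2)
    abs(split_half(tpn, by = "session", window = c(0, 2))$reliability) < 0.1
  }, logical(1)))
  expect_gte(n_ok, 19)

  one_rep <- trial_pattern_array(array(rnorm(40), c(2, 1, 2, 10)))
  expect_error(split_half(one_rep), ">= 2 repetitions")
})

test_that("odd repetition counts put the extra repetition in the first half", {
  resp <- array(rnorm(4 * 5 * 2 * 30), c(4, 5, 2, 30))
  tpa <- trial_pattern_array(resp, spacing = 2)
  expect_message(sh <- split_half(tpa, by = "session", window = c(0, 2)),
                 "3 repetitions in half 1")
  manual1 <- pairwise_similarity(
    build_scene_patterns(trial_pattern_array(resp[, 1:3, , , drop = FALSE],
                                             spacing = 2),
                         window = c(0, 2))$patterns)
  expect_equal(as.numeric(sh$half1), fisher_z(as.numeric(upper_triangle(manual1))),
               tolerance = 1e-12)
})

test_that("behavioral matrices apply catch-trial QC and per-pair log means", {
  # all ratings 4 -> every covered cell is log 4
  rt <- manual_rating_table(c(1, 1, 2, 1), c(2, 3, 3, 1), c(4, 4, 4, 8))
  bm <- behavioral_matrix(rt, 3)
  expect_equal(bm[1, 2], log(4))
  expect_equal(bm[2, 3], log(4))
  expect_true(all(abs(bm[upper.tri(bm)] - log(4)) < 1e-12))

  # failed catch drops that HIT's non-catch rows
  df <- data.frame(
    rater = rep(1:2, each = 11),
    hit = rep(1:2, each = 11),
    scene_a = rep(c(rep(1, 10), 2), 2),
    scene_b = rep(c(rep(2, 10), 2), 2),
    response = c(rep(5, 10), 3,          # rater 1 fails the catch
                 rep(3, 10), 8),         # rater 2 passes
    is_catch = rep(c(rep(FALSE, 10), TRUE), 2))
  expect_message(bm2 <- behavioral_matrix(rating_table(df), 2),
                 "1 HIT\\(s\\)")
  expect_equal(attr(bm2, "hits_dropped"), 1L)
  expect_equal(bm2[1, 2], log(3))        # only rater 2's ratings remain

  # per-pair log-mean oracle on mixed ratings
  rt3 <- manual_rating_table(c(1, 1, 1, 2, 1), c(2, 2, 3, 3, 1),
                             c(2, 7, 4, 1, 8))
  bm3 <- behavioral_matrix(rt3, 3)
  expect_equal(bm3[1, 2], mean(log(c(2, 7))), tolerance = 1e-12)
  expect_equal(bm3[1, 3], log(4))
  expect_equal(bm3[2, 3], log(1))

  # a non-catch response of 8 is retained as a valid rating
  rt4 <- manual_rating_table(c(1, 1), c(2, 1), c(8, 8))
  expect_equal(behavioral_matrix(rt4, 2)[1, 2], log(8))

  # uncovered pairs are missing
  expect_true(is.na(bm3[1, 3]) == FALSE && is.na(behavioral_matrix(
    manual_rating_table(c(1, 1), c(2, 1), c(4, 8)), 3)[1, 3]))
})

test_that("planted bad raters are excluded exactly as generated", {
  true_space <- scenespace:::with_seed(3, rnorm(45))
  rt <- gen_ratings(true_space, n_obs_per_pair = 6, n_bad_raters = 2,
                    seed = 11, hits_per_rater = 4)
  bm <- suppressMessages(behavioral_matrix(rt, 10))
  expect_equal(sort(as.integer(attr(bm, "raters_dropped"))),
               sort(attr(rt, "bad_raters")))
  # without planted bad raters nothing is dropped
  rt0 <- gen_ratings(true_space, 6, n_bad_raters = 0, seed = 12)
  bm0 <- behavioral_matrix(rt0, 10)
  expect_length(attr(bm0, "raters_dropped"), 0)
  expect_equal(attr(bm0, "hits_dropped"), 0L)
})
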