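# Shared fixtures, all generated in code at test time.

# k mutually orthogonal candidate model spaces over n scenes, each scaled so
# its entries have standard deviation `scale` (keeps implied similarity
# matrices diagonally dominant and positive semidefinite).
orthogonal_model_spaces <- function(n, k = 3, seed = 1, scale = 0.1) {
  L <- n * (n - 1) / 2
  scenespace:::with_seed(seed, {
    M <- qr.Q(qr(matrix(rnorm(L * k), L, k))) * sqrt(L) * scale
    lapply(seq_len(k), function(j) M[, j])
  })
}

# deterministic non-constant test image (values in [0, 1])
checker_image <- function(n = 64, seed = 1) {
  scenespace:::with_seed(seed, matrix(runif(n * n), n, n))
}

# small color image
color_image <- function(n = 64, seed = 1) {
  scenespace:::with_seed(seed, array(runif(n * n * 3), c(n, n, 3)))
}

# rating table with hand-controlled content: one rater, one HIT per row set
manual_rating_table <- function(scene_a, scene_b, response,
                                rater = 1L, hit = 1L) {
  k <- length(scene_a)
  rating_table(data.frame(
    rater = rep_len(rater, k), hit = rep_len(hit, k),
    scene_a = scene_a, scene_b = scene_b,
    response = response, is_catch = scene_a == scene_b))
}

# scalar Pearson correlation oracle (explicit formula, no cor())
pearson_oracle <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
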