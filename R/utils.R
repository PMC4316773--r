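# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state.  Every stochastic operation in the
#' package routes its draws through this helper so that generator calls are
#' reproducible and never leak state into the session.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# positive integer scalar check
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

#' Convert a color image to luminance
#'
#' Uses the 0.299/0.587/0.114 luma weights.  Grayscale input (a 2-D matrix)
#' is returned unchanged.
#'
#' @param image numeric matrix (grayscale) or h x w x 3 array with values
#'   that are finite; the usual range is \[0, 1\].
#' @return numeric matrix of intensities.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  if (length(dim(image)) == 3L && dim(image)[3] == 1L) return(image[, , 1])
  stop("`image` must be a matrix or an h x w x 3 array", call. = FALSE)
}

# Vectorized HSV -> RGB on [0,1] inputs; returns list(r, g, b).
# Arguments recycle to a common length.
hsv_to_rgb <- function(h, s, v) {
  n <- max(length(h), length(s), length(v))
  h <- rep_len(as.numeric(h), n)
  s <- rep_len(as.numeric(s), n)
  v <- rep_len(as.numeric(v), n)
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  list(r = r, g = g, b = b)
}

# Hue channel in [0,1) of an h x w x 3 array.
hue_channel <- function(image) {
  if (!(length(dim(image)) == 3L && dim(image)[3] == 3L)) {
    stop("color image (h x w x 3) required", call. = FALSE)
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h / 6
}

# Average a matrix over a g x g grid of blocks (rows/cols partitioned into g
# nearly equal contiguous groups).  Returns a g x g matrix.
block_average <- function(m, g) {
  ri <- cut(seq_len(nrow(m)), g, labels = FALSE)
  ci <- cut(seq_len(ncol(m)), g, labels = FALSE)
  sums <- rowsum(t(rowsum(m, ri)), ci)     # g x g, transposed
  cnt <- tabulate(ri, g) %o% tabulate(ci, g)
  t(sums) / cnt
}

# sample skewness (moment estimator, as commonly reported for ratings)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
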