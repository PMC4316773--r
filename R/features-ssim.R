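# Self-similarity descriptors: local log-polar summaries of the correlation
# surface between a small central patch and its surrounding window.

# displacement set within `radius` of the origin, excluding (0, 0)
ssim_displacements <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d <- d[d$dx^2 + d$dy^2 <= radius^2 & !(d$dx == 0 & d$dy == 0), ]
  d
}

# log-polar bin index (1..n_angles*n_radial) for each displacement
ssim_bins <- function(disp, radius, n_angles, n_radial) {
  ang <- atan2(disp$dy, disp$dx) %% (2 * pi)
  abin <- pmin(floor(ang / (2 * pi / n_angles)), n_angles - 1L)
  edges <- exp(seq(log(1), log(radius + 1e-9), length.out = n_radial + 1))
  rr <- sqrt(disp$dx^2 + disp$dy^2)
  rbin <- pmax(findInterval(rr, edges, rightmost.closed = TRUE), 1L)
  (rbin - 1L) * n_angles + abin + 1L
}

#' Self-similarity descriptors of an image
#'
#' At each sample point, correlates the centered `patch` x `patch` pixel
#' patch with the equally sized patch at every displacement within `radius`
#' pixels (Pearson correlation of the two patch vectors), then pools the
#' correlation surface into a log-polar grid of `n_angles` angular x
#' `n_radial` radial bins by taking the maximum correlation per bin.
#' Correlations are mapped from \[-1, 1\] to \[0, 1\].  Sample points whose
#' window would leave the image are skipped and counted; points whose
#' central patch has zero variance have an undefined correlation surface and
#' are flagged degenerate and excluded.
#'
#' @param image grayscale matrix or color array (luminance is used).
#' @param patch central patch side in pixels (odd).
#' @param radius correlation window radius in pixels.
#' @param stride sampling stride in pixels; ignored when `points` is given.
#' @param points optional 2-column matrix (x, y) of requested sample points.
#' @param n_angles angular bins of the log-polar grid.
#' @param n_radial radial bins of the log-polar grid.
#' @return list with `descriptors` (points x `n_angles * n_radial` matrix),
#'   `points` (data frame of the points kept), `n_skipped` (outside the
#'   valid margin), `n_degenerate` (zero-variance central patches).
#' @export
ssim_descriptors <- function(image, patch = 5, radius = 40, stride = 8,
                             points = NULL, n_angles = 20, n_radial = 4) {
  g <- to_grayscale(image)
  half <- patch %/% 2
  margin <- radius + half
  if (min(dim(g)) <= 2 * radius + patch) {
    stop("image side must exceed 2 * radius + patch", call. = FALSE)
  }
  if (is.null(points)) {
    xs <- seq(margin + 1L, ncol(g) - margin, by = stride)
    ys <- seq(margin + 1L, nrow(g) - margin, by = stride)
    points <- as.matrix(expand.grid(x = xs, y = ys))
    n_skipped <- 0L
  } else {
    points <- as.matrix(points)
    ok <- points[, 1] > margin & points[, 1] <= ncol(g) - margin &
      points[, 2] > margin & points[, 2] <= nrow(g) - margin
    n_skipped <- sum(!ok)
    if (n_skipped) {
      message(sprintf("%d sample point(s) skipped: window exits the image",
                      n_skipped))
    }
    points <- points[ok, , drop = FALSE]
  }
  disp <- ssim_displacements(radius)
  bins <- ssim_bins(disp, radius, n_angles, n_radial)
  nb <- n_angles * n_radial
  n <- nrow(g)
  poff <- as.matrix(expand.grid(py = -half:half, px = -half:half))
  patch_off <- poff[, "py"] + poff[, "px"] * n       # linear offsets
  # linear offsets of every displaced patch pixel: patch x displacement
  doff <- outer(patch_off, disp$dy + disp$dx * n, `+`)

  desc <- matrix(NA_real_, nrow(points), nb)
  degenerate <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    center_lin <- points[p, 2] + (points[p, 1] - 1L) * n
    c0 <- g[center_lin + patch_off]
    c0 <- c0 - mean(c0)
    nc <- sqrt(sum(c0^2))
    if (nc == 0) { degenerate[p] <- TRUE; next }
    P <- matrix(g[center_lin + doff], nrow = length(patch_off))
    P <- P - rep(colMeans(P), each = nrow(P))
    denom <- sqrt(colSums(P^2)) * nc
    r <- as.numeric(crossprod(P, c0))
    r <- ifelse(denom > 0, r / denom, 0)
    pooled <- rep(0, nb)                 # empty bins stay at the midpoint 0
    mx <- tapply(r, bins, max)
    pooled[as.integer(names(mx))] <- mx
    desc[p, ] <- (pooled + 1) / 2
  }
  if (any(degenerate)) {
    message(sprintf("%d degenerate sample point(s) excluded (zero-variance patch)",
                    sum(degenerate)))
  }
  keep <- !degenerate
  list(descriptors = desc[keep, , drop = FALSE],
       points = as.data.frame(points[keep, , drop = FALSE]),
       n_skipped = n_skipped, n_degenerate = sum(degenerate),
       config = list(patch = patch, radius = radius,
                     n_angles = n_angles, n_radial = n_radial))
}
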