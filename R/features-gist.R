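# GIST: global scene descriptor pooling squared oriented band-pass filter
# energies over a coarse spatial grid.

# Oriented log-Gabor-style transfer function on the FFT frequency grid of an
# n x n image.  Hermitian-symmetric (built on orientation modulo pi), so the
# filtered image is real.  Zero at DC: a constant image produces no response.
gabor_bank <- function(n, n_orientations, n_scales,
                       bandwidth_octaves = 0.65, angular_sd = NULL) {
  if (is.null(angular_sd)) angular_sd <- 0.6 * pi / n_orientations
  f1 <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fx <- matrix(f1, n, n)
  fy <- t(fx)
  r <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx) %% pi
  centers <- 0.25 / 2^(seq_len(n_scales) - 1)     # cycles/pixel, log-spaced
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  filters <- vector("list", n_orientations * n_scales)
  i <- 0L
  for (s in seq_len(n_scales)) {
    radial <- exp(-(log2(pmax(r, 1e-12) / centers[s]))^2 /
                    (2 * bandwidth_octaves^2))
    radial[r == 0] <- 0
    for (o in seq_len(n_orientations)) {
      d <- abs(ang - thetas[o])
      d <- pmin(d, pi - d)                        # pi-periodic distance
      i <- i + 1L
      filters[[i]] <- radial * exp(-d^2 / (2 * angular_sd^2))
    }
  }
  list(filters = filters, centers = centers, thetas = thetas,
       n_orientations = n_orientations, n_scales = n_scales)
}

#' GIST descriptor of a scene image
#'
#' Filters the (grayscale) image with a bank of `n_orientations * n_scales`
#' oriented band-pass filters built in the frequency domain, squares each
#' filter's output, and averages the squared response within each cell of a
#' `grid` x `grid` partition.  The concatenation over filters gives a vector
#' of length `n_orientations * n_scales * grid^2` -- 512 dimensions at the
#' defaults (8 orientations, 4 scales, 4 x 4 grid).  The filters have no DC
#' response, so a constant image maps to the zero vector.
#'
#' @param image grayscale matrix or color array (converted by luminance);
#'   must be square and at least `grid` pixels per side.
#' @param n_orientations orientation bins spanning 0 to pi.
#' @param n_scales radial frequency bands, log-spaced from 0.25 cycles/pixel
#'   downwards.
#' @param grid spatial pooling grid per side.
#' @return numeric vector of length `n_orientations * n_scales * grid^2`,
#'   ordered filter-major (all cells of filter 1, then filter 2, ...), with
#'   attribute `method = "gist"`.
#' @export
gist_descriptor <- function(image, n_orientations = 8, n_scales = 4,
                            grid = 4) {
  g <- to_grayscale(image)
  if (nrow(g) != ncol(g)) stop("square image required", call. = FALSE)
  n <- nrow(g)
  if (n < grid) stop("image smaller than the pooling grid", call. = FALSE)
  if (any(!is.finite(g))) stop("image must be finite", call. = FALSE)
  bank <- gabor_bank(n, n_orientations, n_scales)
  G <- stats::fft(g)
  out <- lapply(bank$filters, function(H) {
    resp <- Re(stats::fft(G * H, inverse = TRUE)) / (n * n)
    as.numeric(block_average(resp^2, grid))
  })
  structure(unlist(out), method = "gist",
            config = list(n_orientations = n_orientations,
                          n_scales = n_scales, grid = grid))
}
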