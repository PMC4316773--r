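# Dense local features for bag-of-visual-words quantization: dense SIFT on
# luminance, hue, or RGB channels, and local hue samples for hue histograms.

# 128-d dense SIFT-style descriptor of the (patch x patch) region whose
# top-left corner is (x0, y0): 4x4 spatial sub-cells, 8 orientation bins of
# magnitude-weighted gradients, L2 normalization with 0.2 clipping.  No
# keypoint detection or rotation normalization -- the dense variant.
sift_patch <- function(gx, gy, y0, x0, patch = 16L, n_orient = 8L) {
  sub <- patch %/% 4L
  rows <- y0:(y0 + patch - 1L)
  cols <- x0:(x0 + patch - 1L)
  mg <- sqrt(gx[rows, cols]^2 + gy[rows, cols]^2)
  an <- atan2(gy[rows, cols], gx[rows, cols]) %% (2 * pi)
  ob <- pmin(floor(an / (2 * pi / n_orient)), n_orient - 1L)
  cy <- (row(mg) - 1L) %/% sub
  cx <- (col(mg) - 1L) %/% sub
  key <- ((cy * 4L + cx) * n_orient + ob) + 1L       # 1..128
  v <- numeric(16L * n_orient)
  tab <- rowsum(as.numeric(mg), group = as.integer(key))
  v[as.integer(rownames(tab))] <- tab[, 1]
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v)
  v <- pmin(v / nv, 0.2)
  v / sqrt(sum(v^2))
}

#' Dense local features of an image
#'
#' Samples local descriptors on a regular grid with the given stride:
#'
#' * `dense_sift`: 128-d gradient-orientation histogram descriptor
#'   (4x4 spatial sub-bins x 8 orientation bins) on the luminance channel,
#'   invariant to constant intensity offsets.
#' * `hue_sift`: the same descriptor computed on the hue channel of the HSV
#'   representation.
#' * `rgb_sift`: the descriptor computed on each of R, G, B independently
#'   and concatenated (384-d).
#' * `hue_hist`: the local hue value at each grid point (1-d descriptors),
#'   intended for k-means quantization into a hue histogram.
#'
#' Color variants reject grayscale input.
#'
#' @param image grayscale matrix (dense_sift only) or h x w x 3 array.
#' @param variant one of `"hue_hist"`, `"dense_sift"`, `"hue_sift"`,
#'   `"rgb_sift"`.
#' @param stride sampling stride in pixels.
#' @param patch descriptor support in pixels (multiple of 4).
#' @return list with `descriptors` (points x dims matrix), `points`
#'   (data frame with `x`, `y` of each patch's top-left corner), `variant`.
#' @export
local_color_features <- function(image,
                                 variant = c("hue_hist", "dense_sift",
                                             "hue_sift", "rgb_sift"),
                                 stride = 8, patch = 16) {
  variant <- match.arg(variant)
  is_color <- length(dim(image)) == 3L && dim(image)[3] == 3L
  if (!is_color && variant != "dense_sift") {
    stop(sprintf("variant '%s' requires a color image", variant),
         call. = FALSE)
  }
  if (patch %% 4 != 0) stop("`patch` must be a multiple of 4", call. = FALSE)
  h <- if (is_color) dim(image)[1] else nrow(image)
  w <- if (is_color) dim(image)[2] else ncol(image)
  ys <- seq(1L, h - patch + 1L, by = stride)
  xs <- seq(1L, w - patch + 1L, by = stride)
  pts <- expand.grid(x = xs, y = ys)

  channel_sift <- function(ch) {
    gr <- image_gradients(ch)
    t(mapply(function(x0, y0) sift_patch(gr$gx, gr$gy, y0, x0, patch),
             pts$x, pts$y))
  }
  desc <- switch(variant,
    dense_sift = channel_sift(to_grayscale(image)),
    hue_sift = channel_sift(hue_channel(image)),
    rgb_sift = cbind(channel_sift(image[, , 1]),
                     channel_sift(image[, , 2]),
                     channel_sift(image[, , 3])),
    hue_hist = {
      hch <- hue_channel(image)
      # hue at the patch center
      matrix(hch[cbind(pts$y + patch %/% 2L, pts$x + patch %/% 2L)], ncol = 1L)
    })
  list(descriptors = desc, points = pts, variant = variant,
       config = list(stride = stride, patch = patch))
}
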