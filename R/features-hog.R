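# Histogram-of-oriented-gradients pyramid: per-cell orientation histograms,
# stacked over 2x2 cell blocks, vector-quantized, and pooled over spatial
# pyramid grids of 1x1 (L0), 2x2 (L1), and 4x4 (L2).

# Image gradients by central differences with replicated borders.  Returns
# list(gx, gy); the convention commutes exactly with 90-degree rotation,
# which rotates every gradient vector by 90 degrees.
image_gradients <- function(g) {
  n <- nrow(g); m <- ncol(g)
  right <- g[, c(2:m, m)]; left <- g[, c(1, 1:(m - 1))]
  down <- g[c(2:n, n), ]; up <- g[c(1, 1:(n - 1)), ]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

#' Per-cell oriented-gradient histograms
#'
#' Divides the image into non-overlapping `cell_size` x `cell_size` cells
#' and accumulates magnitude-weighted gradient orientation histograms in
#' each: `n_sensitive` contrast-sensitive bins over the full circle,
#' `n_insensitive` contrast-insensitive bins over the half circle, plus one
#' texture component (total gradient energy).  Bin widths are chosen so a
#' 90-degree image rotation permutes histogram bins exactly.
#'
#' @param image grayscale matrix or color array.
#' @param cell_size cell side in pixels.
#' @param n_sensitive contrast-sensitive orientation bins (360 degrees).
#' @param n_insensitive contrast-insensitive orientation bins (180 degrees).
#' @return list with `cells` (array `[cy, cx, n_sensitive + n_insensitive + 1]`)
#'   and the configuration.
#' @export
hog_cell_histograms <- function(image, cell_size = 8, n_sensitive = 16,
                                n_insensitive = 8) {
  g <- to_grayscale(image)
  if (nrow(g) < 32 || ncol(g) < 32) {
    stop("image must be at least 32 px per side", call. = FALSE)
  }
  gr <- image_gradients(g)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  ang <- atan2(gr$gy, gr$gx) %% (2 * pi)
  ncy <- nrow(g) %/% cell_size
  ncx <- ncol(g) %/% cell_size
  ci_y <- (row(g) - 1L) %/% cell_size + 1L
  ci_x <- (col(g) - 1L) %/% cell_size + 1L
  inside <- ci_y <= ncy & ci_x <= ncx
  cell_id <- (ci_x - 1L) * ncy + ci_y
  sens_bin <- pmin(floor(ang / (2 * pi / n_sensitive)), n_sensitive - 1L)
  insens_bin <- pmin(floor((ang %% pi) / (pi / n_insensitive)),
                     n_insensitive - 1L)
  n_cells <- ncy * ncx
  cells <- array(0, c(ncy, ncx, n_sensitive + n_insensitive + 1L))
  idx <- which(inside & mag > 0)
  acc <- function(bin, offset) {
    key <- bin[idx] * n_cells + cell_id[idx]   # 1 .. nb * n_cells
    tab <- rowsum(mag[idx], group = key)
    k0 <- as.numeric(rownames(tab)) - 1
    cid <- (k0 %% n_cells) + 1L
    b <- k0 %/% n_cells
    cbind(cid, offset + b + 1L, tab[, 1])
  }
  if (length(idx)) {
    for (entry in list(acc(sens_bin, 0L),
                       acc(insens_bin, n_sensitive))) {
      cy <- (entry[, 1] - 1L) %% ncy + 1L
      cx <- (entry[, 1] - 1L) %/% ncy + 1L
      cells[cbind(cy, cx, entry[, 2])] <-
        cells[cbind(cy, cx, entry[, 2])] + entry[, 3]
    }
    en <- rowsum((mag[idx])^2, group = cell_id[idx])
    cid <- as.integer(rownames(en))
    cy <- (cid - 1L) %% ncy + 1L
    cx <- (cid - 1L) %/% ncy + 1L
    cells[cbind(cy, cx, n_sensitive + n_insensitive + 1L)] <- en[, 1]
  }
  list(cells = cells, cell_size = cell_size, n_sensitive = n_sensitive,
       n_insensitive = n_insensitive, n_cells_y = ncy, n_cells_x = ncx)
}

#' Stacked 2x2-block HOG descriptors
#'
#' Stacks the histograms of every spatially overlapping 2x2 group of cells
#' into one local descriptor and L2-normalizes it (zero-gradient blocks stay
#' zero).  These block descriptors are the units that get vector-quantized
#' against a codebook before spatial-pyramid pooling.
#'
#' @param image grayscale matrix or color array.
#' @inheritParams hog_cell_histograms
#' @return list with `descriptors` (blocks x 4*(bins+1) matrix), `centers`
#'   (block centers in pixel coordinates, columns `x`, `y`).
#' @export
hog_block_descriptors <- function(image, cell_size = 8, n_sensitive = 16,
                                  n_insensitive = 8) {
  ch <- hog_cell_histograms(image, cell_size, n_sensitive, n_insensitive)
  ncy <- ch$n_cells_y; ncx <- ch$n_cells_x
  if (ncy < 2 || ncx < 2) stop("image too small for 2x2 cell blocks",
                               call. = FALSE)
  d <- dim(ch$cells)[3]
  blocks <- matrix(0, (ncy - 1) * (ncx - 1), 4L * d)
  centers <- matrix(0, nrow(blocks), 2L,
                    dimnames = list(NULL, c("x", "y")))
  b <- 0L
  for (cx in seq_len(ncx - 1)) {
    for (cy in seq_len(ncy - 1)) {
      b <- b + 1L
      v <- c(ch$cells[cy, cx, ], ch$cells[cy + 1, cx, ],
             ch$cells[cy, cx + 1, ], ch$cells[cy + 1, cx + 1, ])
      nv <- sqrt(sum(v^2))
      blocks[b, ] <- if (nv > 0) v / nv else v
      centers[b, ] <- c(cx * cell_size + 0.5, cy * cell_size + 0.5)
    }
  }
  list(descriptors = blocks, centers = centers,
       image_dim = dim(to_grayscale(image)), cell_size = cell_size)
}

#' Spatial-pyramid HOG descriptor
#'
#' Quantizes the image's 2x2-block HOG descriptors against a codebook and
#' histograms the codeword assignments within each spatial bin of the
#' pyramid: 1x1 at L0, 2x2 at L1, 4x4 at L2.  Each level's vector has
#' length `k * cells`, e.g. `50 * 16 = 800` at L2 with a 50-word codebook,
#' and is L2-normalized.
#'
#' @param image grayscale matrix or color array.
#' @param codebook a [codebook()] trained on block descriptors; omitting it
#'   is a configuration error.
#' @param levels subset of `c("L0", "L1", "L2")`.
#' @param cell_size HOG cell side in pixels.
#' @return named list of per-level numeric vectors.
#' @export
hog_pyramid <- function(image, codebook = NULL, levels = c("L0", "L1", "L2"),
                        cell_size = 8) {
  if (is.null(codebook)) {
    stop("no codebook supplied: train one on block descriptors first (configuration error)",
         call. = FALSE)
  }
  stopifnot(inherits(codebook, "codebook"))
  levels <- match.arg(levels, c("L0", "L1", "L2"), several.ok = TRUE)
  bd <- hog_block_descriptors(image, cell_size = cell_size)
  words <- assign_codebook(bd$descriptors, codebook)
  k <- codebook$k
  out <- lapply(levels, function(lv) {
    gside <- c(L0 = 1L, L1 = 2L, L2 = 4L)[[lv]]
    bx <- pmin(ceiling(bd$centers[, "x"] / bd$image_dim[2] * gside), gside)
    by <- pmin(ceiling(bd$centers[, "y"] / bd$image_dim[1] * gside), gside)
    cellid <- (by - 1L) * gside + bx
    v <- numeric(k * gside^2)
    for (cid in seq_len(gside^2)) {
      sel <- cellid == cid
      if (any(sel)) {
        v[(cid - 1L) * k + seq_len(k)] <- tabulate(words[sel], nbins = k)
      }
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  })
  names(out) <- levels
  out
}
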