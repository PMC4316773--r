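# Bag-of-visual-words: k-means codebooks, nearest-centroid assignment, and
# L2-normalized codeword histograms.

#' Train a visual-word codebook
#'
#' Runs k-means (10 restarts, seeded) on a pool of local descriptors and
#' canonicalizes the centroid order by sorting on the first coordinate (ties
#' broken by subsequent coordinates), so identical inputs and seed always
#' give an identical codebook.  Typical dictionary sizes are
#' k in \{50, 250, 400, 1000\} for local color/SIFT features and 300 for
#' self-similarity descriptors.
#'
#' @param descriptors numeric matrix, one local descriptor per row; needs at
#'   least `k` rows.
#' @param k codebook size.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @param iter_max k-means iteration cap.
#' @return a `codebook`: list with `k`, `centroids` (k x dims), `seed`.
#' @export
train_codebook <- function(descriptors, k, seed = 1, nstart = 10,
                           iter_max = 50) {
  descriptors <- as.matrix(descriptors)
  k <- check_count(k, "k")
  if (nrow(descriptors) < k) {
    stop(sprintf("need >= k descriptors to train a codebook (%d < %d)",
                 nrow(descriptors), k), call. = FALSE)
  }
  if (k == nrow(descriptors)) {
    # exact optimum: every descriptor is its own centroid
    centers <- descriptors
  } else {
    fit <- with_seed(seed, suppressWarnings(
      stats::kmeans(descriptors, centers = k, nstart = nstart,
                    iter.max = iter_max)))
    centers <- fit$centers
  }
  ord <- do.call(order, as.data.frame(centers))
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  structure(list(k = k, centroids = centers, seed = seed),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: k = %d, %d-d descriptors, seed = %s\n",
              x$k, ncol(x$centroids), format(x$seed)))
  invisible(x)
}

#' Nearest-centroid codeword assignment
#'
#' Assigns each descriptor to its nearest centroid in Euclidean distance;
#' ties are broken by the lowest centroid index.
#'
#' @param descriptors points x dims matrix.
#' @param codebook a [train_codebook()] result.
#' @return integer vector of codeword indices in 1..k.
#' @export
assign_codebook <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  x <- as.matrix(descriptors)
  cb <- codebook$centroids
  if (ncol(x) != ncol(cb)) {
    stop(sprintf("descriptor dimensionality (%d) does not match codebook (%d)",
                 ncol(x), ncol(cb)), call. = FALSE)
  }
  d2 <- outer(rowSums(x^2), rep(1, nrow(cb))) - 2 * x %*% t(cb) +
    outer(rep(1, nrow(x)), rowSums(cb^2))
  max.col(-d2, ties.method = "first")
}

#' Bag-of-visual-words histogram
#'
#' Counts nearest-centroid assignments of an image's local descriptors and
#' L2-normalizes the count vector, giving the fixed-length (`k`) image
#' representation used to build similarity matrices.  An empty descriptor
#' set yields the zero vector with a warning.
#'
#' @param descriptors points x dims matrix (possibly 0 rows), or the list
#'   returned by [local_color_features()] / [ssim_descriptors()].
#' @param codebook a [train_codebook()] result.
#' @return numeric vector of length `k` with unit Euclidean norm (or all
#'   zero if no descriptors), attribute `n_descriptors`.
#' @export
bow_histogram <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.list(descriptors) && !is.null(descriptors$descriptors)) {
    descriptors <- descriptors$descriptors
  }
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) == 0L) {
    warning("empty descriptor set: returning the zero histogram",
            call. = FALSE)
    return(structure(numeric(codebook$k), n_descriptors = 0L))
  }
  words <- assign_codebook(descriptors, codebook)
  v <- tabulate(words, nbins = codebook$k)
  structure(v / sqrt(sum(v^2)), n_descriptors = nrow(descriptors))
}
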