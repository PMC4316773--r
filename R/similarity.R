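# First-order similarity spaces: scene x scene correlation matrices and their
# vectorized upper triangles.

#' Construct a similarity-matrix object
#'
#' A `similarity_matrix` is an n x n symmetric matrix of per-pair scene
#' similarities tagged with the method that produced it.  For Pearson-based
#' matrices (`transform = "pearson"`) the diagonal is 1 and off-diagonal
#' cells lie in \[-1, 1\]; behavioral matrices hold mean log-ratings instead
#' and are tagged `"log-rating"`.  Missing cells (`NA`) are allowed and
#' propagate into downstream pairwise-complete correlations.
#'
#' @param m numeric square matrix.
#' @param method character tag naming the measurement method.
#' @param transform one of `"pearson"` or `"log-rating"`.
#' @param tol symmetry tolerance; asymmetry beyond it is an error.
#' @return a `similarity_matrix` object.
#' @export
similarity_matrix <- function(m, method = "unknown", transform = "pearson",
                              tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`m` must be a square matrix", call. = FALSE)
  }
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(asym) && asym > tol) {
    stop(sprintf("matrix is asymmetric beyond tolerance (max |m - t(m)| = %g)",
                 asym), call. = FALSE)
  }
  m[] <- (m + t(m)) / 2
  if (transform == "pearson") {
    off <- m[upper.tri(m)]
    if (any(abs(off) > 1 + 1e-12, na.rm = TRUE)) {
      stop("Pearson similarity cells must lie in [-1, 1]", call. = FALSE)
    }
    diag(m) <- 1
  }
  structure(m, class = c("similarity_matrix", "matrix"),
            method = method, transform = transform)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d scenes, method = %s, transform = %s\n",
              nrow(x), attr(x, "method"), attr(x, "transform")))
  cat(sprintf("  %d missing cells in upper triangle\n",
              sum(is.na(x[upper.tri(x)]))))
  invisible(x)
}

#' Scene-by-scene Pearson similarity from a feature matrix
#'
#' Correlates every pair of rows of a scenes x features matrix, producing the
#' n x n similarity matrix of a scene space under one method.  Rows with zero
#' variance cannot be correlated; all their off-diagonal cells are set
#' missing and reported.
#'
#' @param features numeric matrix, scenes in rows, feature dimensions in
#'   columns; at least 2 rows and 2 columns.
#' @param method character tag stored in the result.
#' @return a [similarity_matrix()] of Pearson r values.
#' @export
pairwise_similarity <- function(features, method = "features") {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2L || ncol(features) < 2L) {
    stop("`features` needs >= 2 scenes and >= 2 dimensions", call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("`features` must be finite", call. = FALSE)
  }
  sds <- apply(features, 1L, stats::sd)
  degenerate <- which(sds == 0)
  r <- suppressWarnings(stats::cor(t(features)))
  if (length(degenerate)) {
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
    warning(sprintf("%d zero-variance scene row(s) produced missing cells: %s",
                    length(degenerate),
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  diag(r) <- 1
  similarity_matrix(r, method = method, transform = "pearson")
}

#' Fisher z transform of correlation coefficients
#'
#' Computes z = atanh(r) = 0.5 log((1 + r) / (1 - r)), the variance-
#' stabilizing transform applied to every similarity value before
#' second-order analysis.  Exact unit correlations, which arise from
#' identical synthetic scenes, would map to infinity and are clamped to
#' `atanh(1 - clamp)`.
#'
#' @param r numeric vector or matrix of correlations with |r| <= 1; `NA`
#'   passes through.
#' @param clamp distance from 1 used for the +/-1 clamp.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, clamp = 1e-7) {
  bad <- abs(r) > 1 & !is.na(r)
  if (any(bad)) {
    stop(sprintf("|r| > 1 is not a correlation (first offender: %g)",
                 r[bad][1]), call. = FALSE)
  }
  rmax <- 1 - clamp
  z <- atanh(pmin(pmax(r, -rmax), rmax))
  if (is.matrix(r)) z <- matrix(z, nrow(r), ncol(r))
  z
}

#' Inverse Fisher transform
#' @param z numeric values on the Fisher scale.
#' @return correlations, `tanh(z)`.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Construct a scene-space vector
#'
#' @param values numeric vector of length n(n-1)/2 in row-major strict
#'   upper-triangle order.
#' @param n scene count.
#' @param transform tag describing the scale of the values.
#' @return a `scene_space` object.
#' @export
scene_space <- function(values, n, transform = "raw r") {
  n <- check_count(n, "n", min = 2L)
  if (length(values) != n * (n - 1L) / 2L) {
    stop(sprintf("length(values) = %d but n = %d needs %d",
                 length(values), n, n * (n - 1L) / 2L), call. = FALSE)
  }
  structure(as.numeric(values), class = "scene_space", n = n,
            transform = transform,
            pair_order = "row-major strict upper triangle, 1-based")
}

#' @export
print.scene_space <- function(x, ...) {
  cat(sprintf("scene_space: %d pairs over %d scenes (%s), %d missing\n",
              length(x), attr(x, "n"), attr(x, "transform"),
              sum(is.na(x))))
  invisible(x)
}

#' Vectorize the upper triangle of a similarity matrix
#'
#' Extracts the strict upper triangle in row-major order — pair (1,2),
#' (1,3), ..., (1,n), (2,3), ... — the fixed pair ordering used by all
#' second-order operations.  For 100 scenes this is the familiar vector of
#' 4950 pairwise values.  Missing cells are preserved as `NA`.
#'
#' @param m a [similarity_matrix()] or plain symmetric square matrix.
#' @param tol symmetry tolerance.
#' @return a [scene_space()] of length n(n-1)/2.
#' @export
upper_triangle <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`m` must be a square matrix", call. = FALSE)
  }
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(asym) && asym > tol) {
    stop("asymmetric input", call. = FALSE)
  }
  n <- nrow(m)
  tm <- t(m)
  transform <- switch(attr(m, "transform") %||% "pearson",
                      "log-rating" = "log-rating", "raw r")
  # row-major strict upper triangle == column-major strict lower of t(m)
  scene_space(tm[lower.tri(tm)], n, transform = transform)
}

#' Rebuild a symmetric matrix from a scene-space vector
#'
#' Inverse of [upper_triangle()]: places the row-major upper-triangle values
#' back into an n x n symmetric matrix with `diag_value` on the diagonal.
#'
#' @param v a [scene_space()] or numeric vector of length n(n-1)/2.
#' @param n scene count (taken from the object when omitted).
#' @param diag_value diagonal fill, default 1.
#' @return a symmetric n x n matrix.
#' @export
reconstruct_similarity <- function(v, n = attr(v, "n"), diag_value = 1) {
  n <- check_count(n, "n", min = 2L)
  stopifnot(length(v) == n * (n - 1L) / 2L)
  m <- matrix(diag_value, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- as.numeric(v)
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-half reliability of a neural scene space
#'
#' Splits the repetitions of a trial array into two disjoint halves (by
#' session, i.e. first half vs. second half of repetitions, or odd vs. even
#' repetitions), reduces each half to a scene space, and reports the Pearson
#' correlation between the two Fisher-transformed spaces as the reliability
#' of the similarity structure.
#'
#' @param trials a [trial_pattern_array()].
#' @param by `"session"` (first half vs. second half of the repetition
#'   sequence) or `"odd_even"`.
#' @param window time window in seconds passed to [build_scene_patterns()].
#' @return list with elements `half1`, `half2` (both [scene_space()] on the
#'   Fisher scale) and `reliability` (Pearson r between them).
#' @export
split_half <- function(trials, by = c("session", "odd_even"),
                       window = c(6, 8)) {
  by <- match.arg(by)
  stopifnot(inherits(trials, "trial_pattern_array"))
  n_rep <- dim(trials$responses)[2]
  if (n_rep < 2L) stop("need >= 2 repetitions to split", call. = FALSE)
  reps <- seq_len(n_rep)
  if (by == "session") {
    cut_at <- ceiling(n_rep / 2)           # odd counts: extra rep in half 1
    first <- reps[reps <= cut_at]
    second <- reps[reps > cut_at]
  } else {
    first <- reps[reps %% 2L == 1L]
    second <- reps[reps %% 2L == 0L]
  }
  if (n_rep %% 2L == 1L) {
    message(sprintf("odd repetition count (%d): %d repetitions in half 1, %d in half 2",
                    n_rep, length(first), length(second)))
  }
  halves <- lapply(list(first, second), function(idx) {
    sub <- trials
    sub$responses <- trials$responses[, idx, , , drop = FALSE]
    pat <- build_scene_patterns(sub, window = window)
    fisher_space(pairwise_similarity(pat$patterns, method = trials$roi))
  })
  r <- stats::cor(halves[[1]], halves[[2]], use = "pairwise.complete.obs")
  list(half1 = halves[[1]], half2 = halves[[2]], reliability = r)
}

#' Fisher-transformed scene space of a similarity matrix
#'
#' Convenience composition `fisher_z(upper_triangle(m))`, the standard
#' preparation of one method's similarity matrix for second-order
#' correlation.
#'
#' @param m a [similarity_matrix()].
#' @return [scene_space()] on the Fisher-z scale.
#' @export
fisher_space <- function(m) {
  v <- upper_triangle(m)
  if (attr(v, "transform") == "log-rating") {
    return(v)      # behavioral spaces stay on the log-rating scale
  }
  scene_space(fisher_z(as.numeric(v)), attr(v, "n"), transform = "Fisher z")
}
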