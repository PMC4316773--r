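# Second-order analysis: correlations between scene spaces, model ranking,
# ordered-block hierarchical regression, and bootstrap model comparison.

#' Correlation between two scene spaces
#'
#' Pearson correlation over the jointly non-missing scene pairs of two
#' vectorized similarity spaces, with a two-sided p-value from the t
#' distribution on `n_complete - 2` degrees of freedom.
#'
#' @param a,b [scene_space()] vectors (or plain numeric) of equal length.
#' @return list with `r`, `p`, `n_complete`.
#' @export
space_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("scene spaces must have equal length", call. = FALSE)
  }
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) {
    stop("fewer than 3 jointly non-missing pairs", call. = FALSE)
  }
  ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_complete = sum(ok))
}

#' Cross-method correlation table
#'
#' All pairwise correlations between a set of scene spaces (e.g. every ROI,
#' behavior, and every computer-vision method), with Bonferroni-style
#' significance flags.  `correction = "bonferroni_pairs"` tests each cell at
#' alpha divided by the number of scene pairs entering the correlations
#' (4950 for 100 scenes); `"bonferroni_m"` divides by `m_family`, the size
#' of a declared comparison family (e.g. 39 correlations in a regression
#' family), defaulting to the number of unique space pairs.
#'
#' @param spaces named list of [scene_space()] vectors of common length.
#' @param correction `"bonferroni_pairs"` or `"bonferroni_m"`.
#' @param alpha family-wise level, default 0.05.
#' @param m_family family size for `"bonferroni_m"`.
#' @return a `cross_method_matrix`: list with `r` (m x m), `p` (m x m),
#'   `significant` (logical m x m), `alpha_cell` (per-cell level), labels.
#' @export
correlation_table <- function(spaces,
                              correction = c("bonferroni_pairs",
                                             "bonferroni_m"),
                              alpha = 0.05, m_family = NULL) {
  correction <- match.arg(correction)
  stopifnot(is.list(spaces), length(spaces) >= 2L)
  lens <- vapply(spaces, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all spaces must share one length", call. = FALSE)
  }
  m <- length(spaces)
  labels <- names(spaces) %||% sprintf("space_%d", seq_len(m))
  divisor <- switch(correction,
    bonferroni_pairs = lens[[1]],
    bonferroni_m = m_family %||% (m * (m - 1) / 2))
  alpha_cell <- alpha / divisor
  r <- diag(1, m); p <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      sc <- space_correlation(spaces[[i]], spaces[[j]])
      r[i, j] <- r[j, i] <- sc$r
      p[i, j] <- p[j, i] <- sc$p
    }
  }
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha_cell,
                 alpha_cell = alpha_cell, correction = correction,
                 labels = labels),
            class = "cross_method_matrix")
}

#' @export
print.cross_method_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("cross_method_matrix: %d spaces, %s at per-cell alpha = %.3g\n",
              length(x$labels), x$correction, x$alpha_cell))
  print(round(x$r, digits))
  invisible(x)
}

#' Rank candidate model spaces against a target space
#'
#' Correlates every model scene space with the target (typically a neural
#' scene space) and sorts models by descending Pearson r.  Ties are broken
#' by label order and reported.
#'
#' @param target [scene_space()] vector.
#' @param models named list of model [scene_space()] vectors.
#' @param top_k how many of the top models to keep (default: all).
#' @return data frame with columns `label`, `r`, `p`, ordered best-first.
#' @export
rank_models <- function(target, models, top_k = length(models)) {
  stopifnot(is.list(models), length(models) >= 1L)
  labels <- names(models) %||% sprintf("model_%d", seq_along(models))
  rs <- vapply(models, function(mv) space_correlation(target, mv)$r,
               numeric(1))
  ps <- vapply(models, function(mv) space_correlation(target, mv)$p,
               numeric(1))
  if (anyDuplicated(rs)) {
    message("tied correlations broken by label order")
  }
  ord <- order(-rs, seq_along(rs))
  out <- data.frame(label = labels[ord], r = unname(rs[ord]),
                    p = unname(ps[ord]), stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Ordered-block hierarchical regression of a scene space
#'
#' Regresses the target scene space on nested ordinary-least-squares models
#' that add one labeled predictor block at a time, in the stated order
#' (e.g. low-level descriptors first, then GIST, geometric classes, semantic
#' attributes, learned attributes, behavior).  Reports the cumulative
#' multiple R after each block, the increment Delta R contributed by the
#' block, and an F test on the R-squared increment at uncorrected and
#' Bonferroni-corrected levels.
#'
#' @param target [scene_space()] vector (no missing entries after
#'   pairwise-complete reduction; rows with any missing value are dropped).
#' @param blocks ordered named list; each element is a matrix (pairs x
#'   predictors) or a list of scene-space vectors entered simultaneously.
#' @param alpha significance level.
#' @param n_comparisons Bonferroni divisor for the corrected flags
#'   (default: number of blocks).
#' @return a `hierarchical_fit`: data frame with one row per block
#'   (`block`, `cumulative_R`, `delta_R`, `R2`, `delta_R2`, `F`, `df1`,
#'   `df2`, `p`, `significant_corrected`, `significant_uncorrected`).
#' @export
hierarchical_regression <- function(target, blocks, alpha = 0.05,
                                    n_comparisons = length(blocks)) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  labels <- names(blocks) %||% sprintf("block_%d", seq_along(blocks))
  y <- as.numeric(target)
  mats <- lapply(blocks, function(b) {
    if (is.list(b) && !is.matrix(b)) b <- do.call(cbind, lapply(b, as.numeric))
    as.matrix(b)
  })
  if (any(vapply(mats, nrow, integer(1)) != length(y))) {
    stop("all predictors must match the target length", call. = FALSE)
  }
  X_all <- do.call(cbind, mats)
  ok <- is.finite(y) & apply(is.finite(X_all), 1L, all)
  y <- y[ok]
  n <- length(y)
  p_total <- ncol(X_all)
  if (p_total + 1L >= n) {
    stop("cumulative predictor count must stay below the observation count",
         call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  res <- data.frame(block = labels, cumulative_R = NA_real_,
                    delta_R = NA_real_, R2 = NA_real_, delta_R2 = NA_real_,
                    F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                    p = NA_real_, significant_corrected = NA,
                    significant_uncorrected = NA, stringsAsFactors = FALSE)
  X <- matrix(1, n, 1)
  r2_prev <- 0
  p_prev <- 0L
  for (k in seq_along(mats)) {
    Xk <- mats[[k]][ok, , drop = FALSE]
    X <- cbind(X, Xk)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop(sprintf("rank-deficient design after adding block '%s'", labels[k]),
           call. = FALSE)
    }
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / sst
    q <- ncol(Xk)
    p_k <- p_prev + q
    df2 <- n - p_k - 1L
    Fstat <- ((r2 - r2_prev) / q) / ((1 - r2) / df2)
    pval <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
    res$cumulative_R[k] <- sqrt(max(r2, 0))
    res$delta_R[k] <- sqrt(max(r2, 0)) - sqrt(max(r2_prev, 0))
    res$R2[k] <- r2
    res$delta_R2[k] <- r2 - r2_prev
    res$F[k] <- Fstat
    res$df1[k] <- q
    res$df2[k] <- df2
    res$p[k] <- pval
    res$significant_uncorrected[k] <- pval < alpha
    res$significant_corrected[k] <- pval < alpha / n_comparisons
    r2_prev <- r2
    p_prev <- p_k
  }
  structure(res, class = c("hierarchical_fit", "data.frame"),
            n_complete = n, alpha = alpha, n_comparisons = n_comparisons)
}

#' @export
print.hierarchical_fit <- function(x, digits = 4, ...) {
  cat(sprintf("hierarchical_fit over %d complete pairs (alpha = %g, corrected by %d)\n",
              attr(x, "n_complete"), attr(x, "alpha"),
              attr(x, "n_comparisons")))
  df <- as.data.frame(x)
  df$cumulative_R <- round(df$cumulative_R, digits)
  df$delta_R <- round(df$delta_R, digits)
  print(df[, c("block", "cumulative_R", "delta_R", "p",
               "significant_corrected")], row.names = FALSE)
  invisible(x)
}

#' Bootstrap test of the difference between two model fits
#'
#' Resamples scene pairs with replacement, jointly across the target and
#' both model spaces, and computes the difference in squared correlation
#' `r2_A - r2_B` in each resample.  The percentile confidence interval at
#' `level` (optionally Bonferroni-widened across a declared family of
#' comparisons) declares the models significantly different when it excludes
#' zero.  Degenerate resamples in which any of the three vectors has zero
#' variance are redrawn and counted.
#'
#' @param target,model_a,model_b [scene_space()] vectors of equal length.
#' @param n_iter bootstrap iterations (>= 100), default 1000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed; identical seeds are bit-reproducible.
#' @param family size of the comparison family for a Bonferroni-widened
#'   interval (1 = no widening).
#' @return a `bootstrap_result`: list with `estimate` (full-sample
#'   `r2_A - r2_B`), `r_a`, `r_b`, `ci` (length 2), `level_nominal`,
#'   `level_used`, `n_iter`, `seed`, `significant`, `n_redrawn`,
#'   `replicates`.
#' @export
bootstrap_model_difference <- function(target, model_a, model_b,
                                       n_iter = 1000, level = 0.95,
                                       seed = 1, family = 1) {
  n_iter <- check_count(n_iter, "n_iter", min = 100L)
  t0 <- as.numeric(target); a0 <- as.numeric(model_a); b0 <- as.numeric(model_b)
  stopifnot(length(t0) == length(a0), length(t0) == length(b0))
  ok <- is.finite(t0) & is.finite(a0) & is.finite(b0)
  t0 <- t0[ok]; a0 <- a0[ok]; b0 <- b0[ok]
  L <- length(t0)
  if (L < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  r_a <- stats::cor(t0, a0)
  r_b <- stats::cor(t0, b0)
  est <- r_a^2 - r_b^2
  level_used <- 1 - (1 - level) / family

  # row-wise Pearson between resampled target and model columns
  boot_diffs <- function(idx_mat) {
    Tm <- matrix(t0[idx_mat], nrow(idx_mat))
    Am <- matrix(a0[idx_mat], nrow(idx_mat))
    Bm <- matrix(b0[idx_mat], nrow(idx_mat))
    center <- function(M) M - rowMeans(M)
    Tm <- center(Tm); Am <- center(Am); Bm <- center(Bm)
    st <- rowSums(Tm^2); sa <- rowSums(Am^2); sb <- rowSums(Bm^2)
    ra <- rowSums(Tm * Am) / sqrt(st * sa)
    rb <- rowSums(Tm * Bm) / sqrt(st * sb)
    list(d = ra^2 - rb^2, degenerate = st == 0 | sa == 0 | sb == 0)
  }

  with_seed(seed, {
    idx <- matrix(sample.int(L, n_iter * L, replace = TRUE), n_iter, L)
    out <- boot_diffs(idx)
    d <- out$d
    bad <- which(out$degenerate | !is.finite(d))
    n_redrawn <- 0L
    while (length(bad)) {
      n_redrawn <- n_redrawn + length(bad)
      idx2 <- matrix(sample.int(L, length(bad) * L, replace = TRUE),
                     length(bad), L)
      out2 <- boot_diffs(idx2)
      d[bad] <- out2$d
      bad <- bad[out2$degenerate | !is.finite(out2$d)]
    }
    if (n_redrawn) {
      message(sprintf("%d degenerate resample(s) redrawn", n_redrawn))
    }
    ci <- unname(stats::quantile(d, c((1 - level_used) / 2,
                                      1 - (1 - level_used) / 2)))
    structure(list(estimate = est, r_a = r_a, r_b = r_b, ci = ci,
                   level_nominal = level, level_used = level_used,
                   n_iter = n_iter, seed = seed,
                   significant = ci[1] > 0 || ci[2] < 0,
                   n_redrawn = n_redrawn, replicates = d),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "bootstrap_result: r2_A - r2_B = %.4g, %d%% CI [%.4g, %.4g] (%d iterations)\n",
    x$estimate, round(100 * x$level_used), x$ci[1], x$ci[2], x$n_iter))
  cat(sprintf("  r_A = %.4g, r_B = %.4g, significant: %s\n",
              x$r_a, x$r_b, x$significant))
  invisible(x)
}
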