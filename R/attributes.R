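# Attribute-score tables (classifier confidences per scene) and the
# exponentiated-variance reweighting applied before correlation, plus the
# geometric-class block-average descriptor.

#' Construct an attribute-score table
#'
#' @param scores scenes x attributes numeric matrix of classifier
#'   confidences; no missing values.
#' @param categories integer category label per scene.
#' @param attribute_names optional column names.
#' @return an `attribute_score_table`.
#' @export
attribute_score_table <- function(scores, categories,
                                  attribute_names = NULL) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("scores must have no missing values", call. = FALSE)
  if (length(categories) != nrow(scores)) {
    stop("one category label per scene row required", call. = FALSE)
  }
  if (is.null(attribute_names)) {
    attribute_names <- sprintf("attr_%03d", seq_len(ncol(scores)))
  }
  colnames(scores) <- attribute_names
  structure(list(scores = scores, categories = as.integer(categories)),
            class = "attribute_score_table")
}

#' @export
print.attribute_score_table <- function(x, ...) {
  cat(sprintf("attribute_score_table: %d scenes x %d attributes, %d categories\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$categories))))
  invisible(x)
}

#' Exponentiated-variance reweighting of attribute scores
#'
#' For each attribute, computes the variance of its per-category mean scores
#' and multiplies the whole column by the exponential of that variance.
#' Attributes that separate categories strongly are up-weighted; attributes
#' constant across categories get weight exp(0) = 1 and are unchanged.  The
#' scaling is positive, so the within-attribute ranking of scenes is
#' preserved.
#'
#' @param table an [attribute_score_table()] with at least 2 categories.
#' @return the reweighted [attribute_score_table()], with attribute
#'   `weights` (the per-column multipliers).
#' @export
reweight_attributes <- function(table) {
  stopifnot(inherits(table, "attribute_score_table"))
  if (length(unique(table$categories)) < 2L) {
    stop("need >= 2 categories to compute between-category variance",
         call. = FALSE)
  }
  cat_means <- rowsum(table$scores, table$categories) /
    as.vector(table(table$categories))
  v <- apply(cat_means, 2L, stats::var)
  w <- exp(v)
  out <- attribute_score_table(sweep(table$scores, 2L, w, `*`),
                               table$categories, colnames(table$scores))
  attr(out, "weights") <- w
  out
}

#' Geometric-class descriptor from probability maps
#'
#' Block-averages each geometric-class probability map (ground, vertical,
#' porous, sky) onto a `grid` x `grid` matrix, where each entry is the mean
#' class probability within that image region; the per-class descriptors
#' have length `grid^2` (64 at the default 8 x 8) and the pooled `all`
#' descriptor is their concatenation.
#'
#' @param prob_maps named list of 2-D probability matrices in \[0, 1\], one
#'   per geometric class (e.g. `gnd`, `vrt`, `por`, `sky`).
#' @param grid output grid side.
#' @return named list of per-class numeric vectors of length `grid^2`, plus
#'   element `all` (concatenation over classes).
#' @export
geom_descriptor <- function(prob_maps, grid = 8) {
  stopifnot(is.list(prob_maps), length(prob_maps) >= 1L)
  grid <- check_count(grid, "grid")
  out <- lapply(prob_maps, function(m) {
    m <- as.matrix(m)
    if (any(m < 0 | m > 1, na.rm = TRUE) || anyNA(m)) {
      stop("probability maps must lie in [0, 1]", call. = FALSE)
    }
    as.numeric(t(block_average(m, grid)))   # row-major over the grid
  })
  out$all <- unlist(out, use.names = FALSE)
  out
}
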