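# Behavioral similarity: rating tables from pairwise-comparison tasks and
# their reduction to a scene x scene matrix of mean log-ratings.

#' Construct a rating table
#'
#' Long-format table of pairwise similarity ratings as collected in a
#' crowd-sourced task: each row is one response by one rater to one scene
#' pair, on a 1-7 similarity scale with 8 reserved for "identical".  Rows are
#' grouped into HITs (task units of 11 trials, exactly one of which is a
#' catch trial showing the same scene twice; its correct answer is 8).
#'
#' @param df data frame with columns `rater` (id), `hit` (task-unit id,
#'   unique within rater), `scene_a`, `scene_b` (1-based scene indices),
#'   `response` (integer 1-8), `is_catch` (logical).
#' @return a `rating_table` (data frame subclass).
#' @export
rating_table <- function(df) {
  need <- c("rater", "hit", "scene_a", "scene_b", "response", "is_catch")
  if (!all(need %in% names(df))) {
    stop("rating table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$response %in% 1:8)) {
    stop("responses must be integers in 1..8", call. = FALSE)
  }
  if (any(df$is_catch & df$scene_a != df$scene_b)) {
    stop("catch rows must compare a scene with itself", call. = FALSE)
  }
  if (any(!df$is_catch & df$scene_a == df$scene_b)) {
    stop("non-catch rows must compare two different scenes", call. = FALSE)
  }
  class(df) <- c("rating_table", class(df))
  df
}

#' Behavioral similarity matrix from a rating table
#'
#' Applies the behavioral quality-control and aggregation pipeline:
#'
#' 1. Any HIT whose catch trial (identical pair) was not answered with 8 is
#'    dropped wholesale — that rater's data for that HIT are removed.
#' 2. Raters who failed at least `rater_catch_threshold` catch trials *and*
#'    whose responses were exclusively 1 or 8 are removed entirely, since it
#'    is ambiguous whether they performed the task at all.
#' 3. Remaining non-catch responses are log-transformed (natural log; the
#'    rating distribution is strongly right-skewed) and averaged per scene
#'    pair.  A response of 8 on a non-catch pair is retained as a valid
#'    (maximal) similarity judgment.
#'
#' Pairs left with zero valid observations become missing cells, which
#' propagate into pairwise-complete second-order correlations.
#'
#' @param ratings a [rating_table()].
#' @param n scene count; cells are indexed by the table's scene indices.
#' @param rater_catch_threshold minimum number of failed catch trials, in
#'   combination with exclusive 1/8 responding, that removes a rater
#'   entirely.  Default 2 ("repeated" failures).
#' @return a [similarity_matrix()] with `transform = "log-rating"`, carrying
#'   attributes `hits_dropped`, `raters_dropped` (ids) and `n_missing_pairs`.
#' @export
behavioral_matrix <- function(ratings, n, rater_catch_threshold = 2L) {
  stopifnot(inherits(ratings, "rating_table"))
  n <- check_count(n, "n", min = 2L)
  df <- as.data.frame(ratings)
  if (any(df$scene_a > n | df$scene_b > n)) {
    stop("scene index exceeds `n`", call. = FALSE)
  }

  fail <- df$is_catch & df$response != 8L
  key <- paste(df$rater, df$hit, sep = "\r")
  failed_hits <- unique(key[fail])

  # whole-rater removal: repeated catch failures + exclusive 1/8 responding
  # (exclusivity judged on the similarity ratings, i.e. non-catch rows)
  n_fail_by_rater <- tapply(fail, df$rater, sum)
  only_extremes <- tapply(df$response[!df$is_catch], df$rater[!df$is_catch],
                          function(r) all(r %in% c(1L, 8L)))
  only_extremes <- only_extremes[names(n_fail_by_rater)]
  bad_raters <- names(n_fail_by_rater)[
    n_fail_by_rater >= rater_catch_threshold & only_extremes]

  keep <- !(key %in% failed_hits) & !(df$rater %in% bad_raters) & !df$is_catch
  kept <- df[keep, , drop = FALSE]
  if (length(bad_raters) || length(failed_hits)) {
    message(sprintf(
      "behavioral exclusions: %d HIT(s) with failed catch trials, %d rater(s) removed entirely",
      length(failed_hits), length(bad_raters)))
  }

  m <- matrix(NA_real_, n, n)
  if (nrow(kept)) {
    i <- pmin(kept$scene_a, kept$scene_b)
    j <- pmax(kept$scene_a, kept$scene_b)
    pair <- (i - 1L) * n + j
    means <- tapply(log(kept$response), pair, mean)
    pj <- as.integer(names(means))
    ii <- (pj - 1L) %/% n + 1L
    jj <- (pj - 1L) %% n + 1L
    m[cbind(ii, jj)] <- means
    m[cbind(jj, ii)] <- means
  }
  diag(m) <- log(8)      # identical scenes sit at the scale's "identical" point
  out <- similarity_matrix(m, method = "behavioral", transform = "log-rating")
  attr(out, "hits_dropped") <- length(failed_hits)
  attr(out, "raters_dropped") <- bad_raters
  attr(out, "n_missing_pairs") <- sum(is.na(out[upper.tri(out)]))
  out
}
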