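# Synthetic data generators.  These emulate the statistical structure the
# analysis assumes -- a categorical stimulus set, attribute-classifier score
# tables, trial-level voxel responses whose induced similarity structure is a
# known mixture of model spaces, and right-skewed pairwise rating tables with
# catch trials -- so every stage of the pipeline can be checked against known
# ground truth.

#' Generate a procedural stimulus set
#'
#' Produces `n_categories * exemplars` color images organized as categories
#' of visually coherent exemplars.  Each category draws its own orientation,
#' spatial frequency, and hue; exemplars within a category jitter those
#' parameters slightly and add independent pixel noise.  Under simple
#' descriptors (GIST, hue histograms) within-category pairs therefore come
#' out more similar than between-category pairs, mimicking a photographic
#' stimulus set of scene categories with two exemplars each.
#'
#' @param n_categories number of scene categories (>= 2).
#' @param exemplars exemplars per category.
#' @param size image side in pixels (>= 32); images are square.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return a `stimulus_set`: list with `images` (list of size x size x 3
#'   arrays in \[0, 1\]), `category_of` (integer vector, scene -> category),
#'   `n_categories`, `exemplars_per_category`.
#' @export
gen_scene_images <- function(n_categories, exemplars, size = 64, seed = 1) {
  n_categories <- check_count(n_categories, "n_categories", min = 2L)
  exemplars <- check_count(exemplars, "exemplars", min = 1L)
  size <- check_count(size, "size", min = 32L)
  with_seed(seed, {
    theta <- (seq_len(n_categories) - 1) * pi / n_categories
    freq <- stats::runif(n_categories, 3, 9)            # cycles per image
    hue <- stats::runif(n_categories)
    u <- matrix(seq(0, 1, length.out = size), size, size)
    v <- t(u)
    images <- vector("list", n_categories * exemplars)
    category_of <- integer(length(images))
    k <- 0L
    for (ci in seq_len(n_categories)) {
      for (ei in seq_len(exemplars)) {
        k <- k + 1L
        th <- theta[ci] + stats::rnorm(1, sd = 0.04)
        f <- freq[ci] * exp(stats::rnorm(1, sd = 0.04))
        ph <- stats::runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * f * (u * cos(th) + v * sin(th)) + ph)
        texture <- 0.25 * sin(2 * pi * 2 * f *
                                (u * cos(th + pi / 2) + v * sin(th + pi / 2)))
        g <- 0.5 + 0.33 * carrier + texture * 0.33 +
          matrix(stats::rnorm(size * size, sd = 0.04), size, size)
        g <- pmin(pmax(g, 0), 1)
        h <- (hue[ci] + stats::rnorm(1, sd = 0.015)) %% 1
        rgb <- hsv_to_rgb(h, 0.55, g)
        img <- array(0, c(size, size, 3))
        img[, , 1] <- rgb$r; img[, , 2] <- rgb$g; img[, , 3] <- rgb$b
        images[[k]] <- img
        category_of[k] <- ci
      }
    }
    structure(list(images = images, category_of = category_of,
                   n_categories = n_categories,
                   exemplars_per_category = exemplars),
              class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d scenes (%d categories x %d exemplars), %dx%d px\n",
              length(x$images), x$n_categories, x$exemplars_per_category,
              dim(x$images[[1]])[1], dim(x$images[[1]])[2]))
  invisible(x)
}

#' Generate an attribute-classifier score table
#'
#' Emulates the output of a bank of attribute classifiers scored on every
#' scene: each attribute has a per-category mean confidence (spread scaled
#' by `category_effect`) plus independent per-exemplar noise.  With a large
#' category effect and small noise, the similarity space of the scores
#' approaches the 0/1 same-category structure.
#'
#' @param stimuli a `stimulus_set` (only its category labels are used).
#' @param n_attributes number of attribute columns (e.g. 84 or 102).
#' @param category_effect standard deviation of the per-category attribute
#'   means.
#' @param noise_sd standard deviation of exemplar-level noise (>= 0).
#' @param seed integer seed.
#' @return an [attribute_score_table()].
#' @export
gen_attribute_scores <- function(stimuli, n_attributes, category_effect = 1,
                                 noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  n_attributes <- check_count(n_attributes, "n_attributes", min = 1L)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  with_seed(seed, {
    ncat <- stimuli$n_categories
    n <- length(stimuli$images)
    cat_means <- matrix(stats::rnorm(ncat * n_attributes, sd = category_effect),
                        ncat, n_attributes)
    scores <- cat_means[stimuli$category_of, , drop = FALSE] +
      matrix(stats::rnorm(n * n_attributes, sd = noise_sd), n, n_attributes)
    attribute_score_table(scores, stimuli$category_of)
  })
}

#' Ground-truth similarity mixture
#'
#' Declares the target similarity structure embedded in synthetic voxel
#' patterns: a nonnegative-weighted mixture of model scene spaces plus
#' voxelwise white noise.  Weights are stored as given and normalized to sum
#' to one at embedding time.
#'
#' @param model_spaces list of [scene_space()] vectors (or plain numeric
#'   vectors) sharing one length n(n-1)/2.
#' @param weights nonnegative weights, one per model space.
#' @param noise_sd standard deviation of additive per-trial noise (>= 0).
#' @param seed integer seed used by [gen_voxel_patterns()].
#' @return a `ground_truth_mixture` object.
#' @export
ground_truth_mixture <- function(model_spaces, weights, noise_sd = 0,
                                 seed = 1) {
  stopifnot(is.list(model_spaces), length(model_spaces) >= 1L,
            length(weights) == length(model_spaces))
  lens <- vapply(model_spaces, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all model spaces must share one length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd == 0 && sum(weights) == 0) {
    stop("at least one weight must be positive when noise_sd = 0",
         call. = FALSE)
  }
  L <- lens[1]
  n <- (1 + sqrt(1 + 8 * L)) / 2
  if (n != round(n)) stop("model space length is not n(n-1)/2", call. = FALSE)
  structure(list(model_spaces = lapply(model_spaces, as.numeric),
                 weights = as.numeric(weights), noise_sd = noise_sd,
                 seed = seed, n_scenes = as.integer(n)),
            class = "ground_truth_mixture")
}

#' Generate trial-level voxel patterns with a known similarity structure
#'
#' Embeds the mixture's target scene x scene similarity matrix into a
#' scenes x voxels signal matrix exactly, using a symmetric eigendecomposition
#' square root of the target matrix applied to voxel basis rows that are
#' orthonormal and mean-centered.  With zero noise, the Pearson correlation
#' matrix of the signal rows *equals* the target matrix, so the pipeline's
#' recovered scene space matches the generating mixture.  Each trial
#' (repetition x timepoint) observes the signal scaled by a peak-window
#' amplitude profile plus independent Gaussian noise; timepoints outside the
#' peak window carry attenuated signal, mimicking the rise and fall of a
#' slow event-related response sampled every 2 s.
#'
#' If the requested mixture implies a similarity matrix that is not positive
#' semidefinite, it cannot be realized by any pattern set; the matrix is
#' projected to the nearest positive-semidefinite correlation matrix and the
#' adjustment is reported as a warning (attribute `psd_adjusted`).
#'
#' @param mixture a [ground_truth_mixture()].
#' @param n_voxels number of voxels (must exceed the scene count so the
#'   embedding has room to be exact).
#' @param n_repetitions stimulus repetitions (e.g. 6 trials per scene).
#' @param n_timepoints samples per trial epoch, spaced `spacing` seconds
#'   apart starting at 0 s.
#' @param peak_window closed time window (seconds) carrying full-amplitude
#'   signal; other timepoints are scaled by `attenuation`.
#' @param spacing sampling interval in seconds.
#' @param attenuation signal multiplier outside the peak window.
#' @param roi label stored on the output.
#' @return a [trial_pattern_array()] with attribute `signal` (the embedded
#'   scenes x voxels matrix) and `target_similarity` (the realized target).
#' @export
gen_voxel_patterns <- function(mixture, n_voxels = 200, n_repetitions = 6,
                               n_timepoints = 5, peak_window = c(6, 8),
                               spacing = 2, attenuation = 0.3,
                               roi = "synthetic") {
  stopifnot(inherits(mixture, "ground_truth_mixture"))
  n <- mixture$n_scenes
  n_voxels <- check_count(n_voxels, "n_voxels", min = 2L)
  if (n_voxels < n + 1L) {
    stop(sprintf("need n_voxels >= %d (scenes + 1) for an exact embedding", n + 1L),
         call. = FALSE)
  }
  n_repetitions <- check_count(n_repetitions, "n_repetitions")
  n_timepoints <- check_count(n_timepoints, "n_timepoints")

  w <- mixture$weights
  off <- if (sum(w) > 0) {
    Reduce(`+`, Map(`*`, mixture$model_spaces, w / sum(w)))
  } else {
    numeric(length(mixture$model_spaces[[1]]))
  }
  S <- reconstruct_similarity(off, n = n)
  eg <- eigen(S, symmetric = TRUE)
  psd_adjusted <- FALSE
  if (min(eg$values) < -1e-10 * max(abs(eg$values))) {
    warning(sprintf(
      "requested mixture is not positive semidefinite (min eigenvalue %.3g); projecting to the nearest realizable correlation matrix",
      min(eg$values)), call. = FALSE)
    vals <- pmax(eg$values, 0)
    S <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(S))
    S <- S / (d %o% d)
    eg <- eigen(S, symmetric = TRUE)
    psd_adjusted <- TRUE
  }
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))

  with_seed(mixture$seed, {
    # voxel basis: n orthonormal rows, each orthogonal to the all-ones
    # vector, so row means are 0 and sample correlations hit S exactly
    A <- matrix(stats::rnorm(n_voxels * n), n_voxels, n)
    A <- scale(A, center = TRUE, scale = FALSE)
    G <- t(qr.Q(qr(A)))
    X <- sqrt(n_voxels - 1) * (L %*% G)      # scenes x voxels signal

    onsets <- (seq_len(n_timepoints) - 1) * spacing
    amp <- ifelse(onsets >= peak_window[1] & onsets <= peak_window[2],
                  1, attenuation)
    resp <- array(0, c(n, n_repetitions, n_timepoints, n_voxels))
    for (tt in seq_len(n_timepoints)) {
      for (rr in seq_len(n_repetitions)) {
        noise <- if (mixture$noise_sd > 0) {
          matrix(stats::rnorm(n * n_voxels, sd = mixture$noise_sd), n, n_voxels)
        } else 0
        resp[, rr, tt, ] <- amp[tt] * X + noise
      }
    }
    out <- trial_pattern_array(resp, spacing = spacing, roi = roi)
    attr(out, "signal") <- X
    attr(out, "target_similarity") <- S
    attr(out, "psd_adjusted") <- psd_adjusted
    out
  })
}

#' Generate a pairwise similarity rating table
#'
#' Simulates a crowd-sourced pairwise-comparison experiment over the scenes
#' implied by `true_space`: every unordered scene pair is rated
#' `n_obs_per_pair` times on a 1-7 scale.  Responses are a monotone
#' discretization of the true similarity with right-skewed noise -- most
#' pairs are judged "different", so low responses dominate and the pooled
#' distribution has strong positive skew, which motivates the log transform
#' applied downstream.  Trials are packed into HITs of 11 rows, each holding
#' exactly one identical-pair catch trial whose correct answer is 8.
#'
#' `n_bad_raters` raters are planted as inattentive: they answer every catch
#' trial incorrectly and use only the extreme responses 1 and 8, matching
#' the whole-rater exclusion rule of [behavioral_matrix()].
#'
#' @param true_space [scene_space()] (or numeric vector of length n(n-1)/2)
#'   of true pairwise similarities; only its rank order matters.
#' @param n_obs_per_pair target observations per pair (>= 1).
#' @param n_bad_raters number of planted inattentive raters.
#' @param seed integer seed.
#' @param hits_per_rater HITs completed per rater (>= 2 so that planted bad
#'   raters accumulate repeated catch failures).
#' @return a [rating_table()] with attribute `bad_raters` (planted ids).
#' @export
gen_ratings <- function(true_space, n_obs_per_pair = 20, n_bad_raters = 0,
                        seed = 1, hits_per_rater = 17) {
  n_obs_per_pair <- check_count(n_obs_per_pair, "n_obs_per_pair")
  hits_per_rater <- check_count(hits_per_rater, "hits_per_rater", min = 2L)
  v <- as.numeric(true_space)
  L <- length(v)
  n <- (1 + sqrt(1 + 8 * L)) / 2
  if (n != round(n)) stop("`true_space` length is not n(n-1)/2", call. = FALSE)
  n <- as.integer(n)

  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(pair_idx[, 1], pair_idx[, 2])    # row-major pair order
  pa <- pair_idx[ord, 1]; pb <- pair_idx[ord, 2]
  sim01 <- (rank(v, ties.method = "average") - 0.5) / L

  with_seed(seed, {
    obs_pair <- sample(rep(seq_len(L), n_obs_per_pair))
    n_obs <- length(obs_pair)
    n_hits <- ceiling(n_obs / 10)
    n_raters <- ceiling(n_hits / hits_per_rater)
    if (n_bad_raters > n_raters) {
      stop("more bad raters requested than raters in the design", call. = FALSE)
    }
    bad <- seq_len(n_bad_raters)

    hit_of_obs <- ceiling(seq_len(n_obs) / 10)
    rater_of_hit <- (seq_len(n_hits) - 1L) %/% hits_per_rater + 1L
    obs_rater <- rater_of_hit[hit_of_obs]
    is_bad <- obs_rater %in% bad

    # non-catch responses: right-skewed monotone discretization of the true
    # similarity (shifted truncated Poisson, calibrated so pooled responses
    # show skewness near 2.7); bad raters press only 1 or 8
    s <- sim01[obs_pair]
    resp <- pmin(1L + stats::rpois(n_obs, 0.04 + 4.5 * s^8), 7L)
    if (any(is_bad)) {
      resp[is_bad] <- sample(c(1L, 8L), sum(is_bad), replace = TRUE)
    }
    # one catch row per HIT; bad raters always answer it incorrectly
    catch_scene <- sample.int(n, n_hits, replace = TRUE)
    catch_resp <- rep(8L, n_hits)
    bad_hits <- rater_of_hit %in% bad
    if (any(bad_hits)) {
      catch_resp[bad_hits] <- sample.int(7L, sum(bad_hits), replace = TRUE)
    }

    df <- data.frame(
      rater = c(obs_rater, rater_of_hit),
      hit = c(hit_of_obs, seq_len(n_hits)),
      scene_a = c(pa[obs_pair], catch_scene),
      scene_b = c(pb[obs_pair], catch_scene),
      response = c(resp, catch_resp),
      is_catch = c(rep(FALSE, n_obs), rep(TRUE, n_hits)))
    df <- df[order(df$hit, stats::runif(nrow(df))), ]  # catch at random slot
    rownames(df) <- NULL
    out <- rating_table(df)
    attr(out, "bad_raters") <- bad
    out
  })
}

#' Generate synthetic geometric-class probability maps
#'
#' Produces per-scene probability maps for the geometric classes ground
#' (`gnd`), vertical (`vrt`), porous (`por`), and `sky`, summing to one at
#' every pixel.  Maps combine a vertical layout prior (sky mass at the top,
#' ground at the bottom), a per-category class bias, and smooth noise, so
#' that scenes of one category share geometric layout.  These stand in for
#' the output of a geometric-context classifier, which the package does not
#' train.
#'
#' @param stimuli a `stimulus_set` (category labels drive the class biases).
#' @param map_size side of the square maps in pixels.
#' @param seed integer seed.
#' @return list (one element per scene) of named lists of `map_size` x
#'   `map_size` matrices for classes `gnd`, `vrt`, `por`, `sky`.
#' @export
gen_geom_maps <- function(stimuli, map_size = 32, seed = 1) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  map_size <- check_count(map_size, "map_size", min = 8L)
  classes <- c("gnd", "vrt", "por", "sky")
  with_seed(seed, {
    ncat <- stimuli$n_categories
    bias <- matrix(stats::rnorm(ncat * 4, sd = 0.8), ncat, 4)
    y <- matrix(seq(-1, 1, length.out = map_size), map_size, map_size)
    layout <- list(gnd = y, vrt = 0 * y, por = 0.3 * y, sky = -y)
    lapply(seq_along(stimuli$images), function(i) {
      ci <- stimuli$category_of[i]
      ri <- ceiling(seq_len(map_size) / (map_size / 4))
      logits <- lapply(seq_along(classes), function(k) {
        smooth <- matrix(stats::rnorm(16, sd = 0.5), 4, 4)
        bias[ci, k] + 1.5 * layout[[k]] + smooth[ri, ri]
      })
      z <- lapply(logits, exp)
      tot <- Reduce(`+`, z)
      maps <- lapply(z, function(e) e / tot)
      names(maps) <- classes
      maps
    })
  })
}
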