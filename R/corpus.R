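#' Read a corpus manifest of annotation files
#'
#' The manifest is a JSON array of tracks, each with an `annotations` array:
#' ```json
#' [{"track": "t1",
#'   "annotations": [
#'     {"annotator": "1", "format": "interval_lab",
#'      "files": {"coarse": "t1/a1_coarse.lab", "fine": "t1/a1_fine.lab"}}
#'   ]}]
#' ```
#' File paths are resolved relative to the manifest's directory. Annotations
#' that fail to read or validate are skipped with a warning, so one corrupt
#' file does not abort a corpus run.
#'
#' @param path Path to the manifest JSON file.
#' @param levels Optional level-name selection passed to [read_annotation()].
#' @return A tibble with columns `track`, `annotator` and a `hierarchy`
#'   list-column, ready for [corpus_scores()].
#' @export
read_corpus_manifest <- function(path, levels = NULL) {
  spec <- jsonlite::read_json(path)
  base <- dirname(normalizePath(path))
  rows <- purrr::map(spec, function(tr) {
    purrr::map(tr$annotations, function(ann) {
      files <- unlist(ann$files)
      h <- tryCatch(
        read_annotation(setNames(file.path(base, files), names(files)),
                        format = ann$format %||% "interval_lab",
                        levels = levels),
        error = function(e) {
          warn(sprintf("skipping annotation %s/%s: %s",
                       tr$track, ann$annotator, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(h)) return(NULL)
      tibble(track = as.character(tr$track),
             annotator = as.character(ann$annotator),
             hierarchy = list(h))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Score all annotator pairs of a corpus
#'
#' For every unordered pair of annotators of each track, computes the
#' hierarchical L-scores plus, per common level, the flat pairwise and NCE
#' scores, and the maximum and minimum of the pairwise F-measure across
#' levels. A track with `k` annotators contributes `choose(k, 2)` pairs
#' (e.g. all 10 pairs for a 5-annotator track). Results are returned in long
#' form; pair order within a track follows the row order of `corpus`, and
#' shuffling the input rows changes no values.
#'
#' @param corpus A tibble with columns `track`, `annotator` and a
#'   `hierarchy` list-column (e.g. from [read_corpus_manifest()] or
#'   [synthetic_corpus()]).
#' @param frame_rate Frame sampling rate in Hz for all metrics.
#' @param ... Passed to [align_pair()].
#' @return A tibble of class `hierseg_scores` with columns `track`,
#'   `annotator_ref`, `annotator_est`, `metric`, `level` (NA for
#'   whole-hierarchy metrics) and `value`.
#' @export
corpus_scores <- function(corpus, frame_rate = 10, ...) {
  req <- c("track", "annotator", "hierarchy")
  if (!all(req %in% names(corpus))) {
    abort("`corpus` needs columns track, annotator, hierarchy")
  }
  corpus <- dplyr::arrange(as_tibble(corpus), .data$track, .data$annotator)
  out <- purrr::map(split(corpus, corpus$track), function(tr) {
    k <- nrow(tr)
    if (k < 2) return(NULL)
    pairs <- utils::combn(k, 2)
    purrr::map(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      res <- tryCatch(
        compare_hierarchies(tr$hierarchy[[i]], tr$hierarchy[[j]],
                            frame_rate = frame_rate, ...),
        error = function(e) {
          warn(sprintf("skipping pair %s: %s/%s: %s", tr$track[1],
                       tr$annotator[i], tr$annotator[j], conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::mutate(res, track = tr$track[1],
                    annotator_ref = tr$annotator[i],
                    annotator_est = tr$annotator[j],
                    .before = 1)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  class(out) <- c("hierseg_scores", class(tibble()))
  out
}

#' All agreement metrics for one annotation pair
#'
#' Computes the full metric battery between two hierarchies of the same
#' recording: the hierarchical L-scores, the flat pairwise and NCE scores at
#' every common level, and the maximum/minimum pairwise F across levels.
#'
#' @inheritParams l_scores
#' @return A long tibble with columns `metric`, `level` (NA for
#'   whole-hierarchy metrics) and `value`.
#' @examples
#' h1 <- random_hierarchy(duration = 60, seed = 1)
#' h2 <- random_hierarchy(duration = 60, seed = 2)
#' compare_hierarchies(h1, h2)
#' @export
compare_hierarchies <- function(h_ref, h_est, frame_rate = 10, ...) {
  grids <- align_pair(h_ref, h_est, frame_rate = frame_rate, ...)
  l <- l_scores_from_counts(
    triple_counts(meet_matrix(grids$ref), meet_matrix(grids$est)))
  depth <- min(nrow(grids$ref), nrow(grids$est))
  per_level <- purrr::map(seq_len(depth), function(k) {
    ref_k <- unclass(grids$ref)[k, ]
    est_k <- unclass(grids$est)[k, ]
    pw <- pairwise_scores(ref_k, est_k)
    nc <- nce_scores(ref_k, est_k)
    tibble(
      metric = c("pairwise_precision", "pairwise_recall", "pairwise_f",
                 "nce_over", "nce_under", "nce_f"),
      level = k,
      value = c(pw$precision, pw$recall, pw$f, nc$precision, nc$recall, nc$f)
    )
  })
  per_level <- dplyr::bind_rows(per_level)
  f_by_level <- per_level$value[per_level$metric == "pairwise_f"]
  dplyr::bind_rows(
    tibble(metric = c("l_precision", "l_recall", "l_measure"),
           level = NA_integer_,
           value = c(l$l_precision, l$l_recall, l$l_measure)),
    per_level,
    tibble(metric = c("pairwise_f_max", "pairwise_f_min"),
           level = NA_integer_,
           value = c(max(f_by_level), min(f_by_level)))
  )
}

#' Median-quadrant analysis of two paired score samples
#'
#' Splits the scatter of paired scores `(x, y)` into quadrants I-IV along
#' the per-axis medians: quadrant I is high-x/high-y, II low-x/high-y, III
#' low-x/low-y, IV high-x/low-y. A point lying exactly on a median line is
#' assigned to the lower half of that axis. Besides the unconditional
#' quadrant fractions, the fractions of low/high `y` conditioned on each `x`
#' half are reported, matching statements of the form "of the points below
#' the x median, this share lie below the y median".
#'
#' @param x,y Equal-length paired numeric samples, `n >= 2`.
#' @return An object of class `hierseg_quadrants`: list with `median_x`,
#'   `median_y`, `n`, `fractions` (named I-IV, summing to 1) and
#'   `conditional` (tibble with one row per `x` half). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' q <- quadrant_analysis(runif(100), runif(100))
#' tidy(q)
#' @export
quadrant_analysis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2) abort("need at least 2 points")
  if (anyNA(x) || anyNA(y)) abort("samples contain missing values")
  mx <- median(x)
  my <- median(y)
  x_high <- x > mx   # ties go to the lower half
  y_high <- y > my
  quadrant <- dplyr::case_when(
    x_high & y_high ~ "I",
    !x_high & y_high ~ "II",
    !x_high & !y_high ~ "III",
    TRUE ~ "IV"
  )
  counts <- table(factor(quadrant, levels = c("I", "II", "III", "IV")))
  conditional <- purrr::map(c(low = FALSE, high = TRUE), function(side) {
    sel <- x_high == side
    tibble(x_half = if (side) "high" else "low",
           n = sum(sel),
           p_y_low = if (any(sel)) mean(!y_high[sel]) else NA_real_,
           p_y_high = if (any(sel)) mean(y_high[sel]) else NA_real_)
  })
  structure(
    list(median_x = mx, median_y = my, n = length(x),
         fractions = setNames(as.vector(counts) / length(x), names(counts)),
         conditional = dplyr::bind_rows(conditional),
         points = tibble(x = x, y = y, quadrant = quadrant)),
    class = "hierseg_quadrants"
  )
}

#' @export
print.hierseg_quadrants <- function(x, ...) {
  cat(sprintf("<hierseg_quadrants> n = %d, medians (%.3f, %.3f)\n",
              x$n, x$median_x, x$median_y))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute difference between the empirical cumulative
#' distribution functions of two score samples: 0 for identical samples, 1
#' for samples with disjoint supports. Used to compare an algorithm's score
#' distribution against the inter-annotator distribution; only the statistic
#' (not a p-value) is reported, since the samples are not independent across
#' tracks.
#'
#' @param a,b Non-empty numeric samples.
#' @return The statistic `K` in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("samples must be non-empty")
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `trials` times, applies `statistic`,
#' and returns the percentile interval at the requested level. Reproducible
#' under a fixed `seed`; a zero-variance sample yields the degenerate
#' interval `[x, x]`.
#'
#' @param values Numeric sample.
#' @param statistic Summary function, e.g. `mean` or `median`.
#' @param trials Number of bootstrap resamples.
#' @param level Coverage level, default 0.95.
#' @param seed Optional integer seed (sets the RNG via `set.seed()`).
#' @return A one-row tibble with columns `lower`, `upper`, `level`, `trials`.
#' @export
bootstrap_ci <- function(values, statistic = mean, trials = 500,
                         level = 0.95, seed = NULL) {
  if (length(values) == 0) abort("`values` must be non-empty")
  if (trials < 1) abort("`trials` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  stats <- vapply(seq_len(trials), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- quantile(stats, c(alpha, 1 - alpha), names = FALSE)
  tibble(lower = q[1], upper = q[2], level = level, trials = trials)
}
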