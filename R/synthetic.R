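#' Generate a random hierarchical segmentation
#'
#' Emulates a coarse/fine annotation of a pop-length recording. Per level,
#' interior boundaries are drawn from a Poisson process with the given rate
#' (so the expected number of top-level segments is
#' `1 + boundary_rate * duration / 60`), and labels are drawn uniformly from
#' a level-local alphabet, adjacent repeats allowed. With `nested = TRUE`
#' (the default, matching the approximately nested coarse/fine annotations
#' of real corpora) each deeper level keeps all boundaries of the level
#' above and adds its own; with `nested = FALSE` levels are independent,
#' which exercises the max-over-levels semantics of the meet.
#'
#' Defaults describe a typical corpus track: 180 s, two stored levels,
#' 4 boundaries per minute per level, 5 labels per level.
#'
#' @param duration Track length in seconds.
#' @param depth Number of stored levels.
#' @param boundary_rate Expected interior boundaries per minute per level.
#' @param alphabet_size Number of distinct labels available per level.
#' @param nested Whether deeper levels subdivide the level above.
#' @param seed Optional integer seed for reproducibility.
#' @return A hierarchy tibble (see [as_hierarchy()]).
#' @examples
#' h <- random_hierarchy(duration = 60, depth = 2, seed = 1)
#' hier_depth(h)
#' @export
random_hierarchy <- function(duration = 180, depth = 2, boundary_rate = 4,
                             alphabet_size = 5, nested = TRUE, seed = NULL) {
  if (duration <= 0) abort("`duration` must be positive")
  if (depth < 1) abort("`depth` must be >= 1")
  if (alphabet_size < 1) abort("`alphabet_size` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  draw_interior <- function() {
    k <- rpois(1, boundary_rate * duration / 60)
    sort(runif(k, 0, duration))
  }
  prev <- numeric(0)
  levels <- vector("list", depth)
  for (lv in seq_len(depth)) {
    if (nested) {
      # parent boundaries are kept verbatim; new draws too close to one
      # (or to each other) are dropped, so nesting is exact
      fresh <- tidy_boundaries(draw_interior(), duration)
      if (length(prev) > 0 && length(fresh) > 0) {
        fresh <- fresh[vapply(fresh, function(b) min(abs(b - prev)) > 0.05,
                              logical(1))]
      }
      interior <- sort(c(prev, fresh))
    } else {
      interior <- tidy_boundaries(draw_interior(), duration)
    }
    bounds <- c(0, interior, duration)
    labs <- sample(level_alphabet(lv, alphabet_size),
                   length(bounds) - 1, replace = TRUE)
    levels[[lv]] <- tibble(level = lv, start = bounds[-length(bounds)],
                           end = bounds[-1], label = labs)
    if (nested) prev <- interior
  }
  as_hierarchy(dplyr::bind_rows(levels))
}

# drop boundaries closer than 50 ms to a neighbor or the track edges, so
# generated hierarchies always pass validation comfortably
tidy_boundaries <- function(b, duration, min_gap = 0.05) {
  b <- b[b > min_gap & b < duration - min_gap]
  if (length(b) > 1) b <- b[c(TRUE, diff(b) > min_gap)]
  b
}

level_alphabet <- function(level, size) {
  base <- if (level == 1) LETTERS else if (level == 2) letters else NULL
  if (!is.null(base) && size <= length(base)) return(base[seq_len(size)])
  paste0("L", level, ".", seq_len(size))
}

#' Perturb a hierarchy in a controlled way
#'
#' Five perturbation kinds probe specific invariances of the metrics:
#' \describe{
#'   \item{`permute_labels`}{bijectively renames the labels within each
#'     level; every label-agreement metric should be unchanged.}
#'   \item{`duplicate_level`}{inserts an exact copy of level `amount`
#'     (default: the deepest) — a depth-alignment discrepancy that the
#'     L-scores are designed to ignore.}
#'   \item{`refine`}{appends a new deepest level that splits every deepest
#'     segment in two with globally fresh labels; L-recall of the original
#'     against the refined hierarchy stays 1.}
#'   \item{`jitter_boundaries`}{moves every interior boundary by an
#'     independent uniform offset in `[-amount, amount]` seconds (default
#'     0.5), clipped so segments keep positive length.}
#'   \item{`relabel_noise`}{independently reassigns each segment's label
#'     with probability `amount` (default 0.2), drawing uniformly from the
#'     level's label set.}
#' }
#'
#' @param h A hierarchy tibble.
#' @param kind Perturbation kind; see Details.
#' @param amount Kind-specific intensity (see above).
#' @param seed Optional integer seed.
#' @return A perturbed hierarchy tibble.
#' @export
perturb_hierarchy <- function(h,
                              kind = c("permute_labels", "duplicate_level",
                                       "refine", "jitter_boundaries",
                                       "relabel_noise"),
                              amount = NULL, seed = NULL) {
  h <- as_hierarchy(h)
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  m <- hier_depth(h)
  out <- switch(kind,
    permute_labels = {
      parts <- lapply(split(h, h$level), function(seg) {
        u <- unique(seg$label)
        seg$label <- sample(u)[match(seg$label, u)]
        seg
      })
      dplyr::bind_rows(parts)
    },
    duplicate_level = {
      k <- if (is.null(amount)) m else as.integer(amount)
      if (k < 1 || k > m) abort(sprintf("no level %d to duplicate", k))
      dup <- h[h$level == k, ]
      dup$level <- k + 0.5   # renumbered by as_hierarchy
      dplyr::bind_rows(h, dup)
    },
    refine = {
      deepest <- h[h$level == m, ]
      pieces <- purrr::map(seq_len(nrow(deepest)), function(i) {
        s <- deepest$start[i]; e <- deepest$end[i]
        cut <- s + (e - s) * runif(1, 0.25, 0.75)
        tibble(level = m + 1,
               start = c(s, cut), end = c(cut, e),
               label = paste0("r", 2 * i - 1:0))
      })
      dplyr::bind_rows(h, dplyr::bind_rows(pieces))
    },
    jitter_boundaries = {
      a <- amount %||% 0.5
      parts <- lapply(split(h, h$level), function(seg) {
        n <- nrow(seg)
        if (n > 1) {
          b <- seg$end[-n]
          b <- b + runif(n - 1, -a, a)
          # sequential clipping keeps boundaries ordered with positive gaps
          lo <- c(0, rep(NA, n - 2))
          for (i in seq_along(b)) {
            lower <- if (i == 1) 0 else b[i - 1]
            upper <- if (i == length(b)) hier_duration(seg) else seg$end[i + 1]
            b[i] <- min(max(b[i], lower + 0.01), upper - 0.01)
          }
          seg$end[-n] <- b
          seg$start[-1] <- b
        }
        seg
      })
      dplyr::bind_rows(parts)
    },
    relabel_noise = {
      a <- amount %||% 0.2
      parts <- lapply(split(h, h$level), function(seg) {
        u <- unique(seg$label)
        flip <- runif(nrow(seg)) < a
        seg$label[flip] <- sample(u, sum(flip), replace = TRUE)
        seg
      })
      dplyr::bind_rows(parts)
    }
  )
  as_hierarchy(out)
}

#' Structure-correlated synthetic feature matrices
#'
#' Emulates the block structure that self-similarity matrices of real audio
#' exhibit: for each feature kind, every label of the hierarchy's deepest
#' level is assigned a random prototype column (standard normal entries),
#' and each frame receives its segment's prototype plus independent Gaussian
#' noise of the given scale. With `noise_scale = 0` the resulting
#' self-similarity matrix is exactly block-valued on same-label frame pairs;
#' increasing noise progressively erodes the correlation between the
#' features and the annotation's meet matrix.
#'
#' Output dimensions match the real extractors after [prepare_features()]:
#' 384 (tempo), 33 (rhythm), 36 (chroma), 60 (mfcc).
#'
#' @param h A hierarchy tibble.
#' @param frame_rate Frame rate of the synthetic feature grid, default 4 Hz.
#' @param noise_scale Standard deviation of the additive noise relative to
#'   the unit-scale prototypes.
#' @param seed Optional integer seed.
#' @return A named list of four `hierseg_features` matrices
#'   (`tempo`, `rhythm`, `chroma`, `mfcc`).
#' @export
planted_features <- function(h, frame_rate = 4, noise_scale = 0.5,
                             seed = NULL) {
  h <- as_hierarchy(h)
  if (!is.null(seed)) set.seed(seed)
  grid <- sample_labels(h, frame_rate)
  lab <- unclass(grid)[nrow(grid), ]
  n <- length(lab)
  k <- max(lab)
  dims <- c(tempo = 384L, rhythm = 33L, chroma = 36L, mfcc = 60L)
  purrr::imap(as.list(dims), function(d, kind) {
    proto <- matrix(rnorm(d * k), d, k)
    x <- proto[, lab, drop = FALSE] + noise_scale * matrix(rnorm(d * n), d, n)
    new_features(x, kind, frame_rate)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Builds `n_tracks` tracks, each with `n_annotators` annotations derived
#' from one planted hierarchy per track: every annotator's version applies
#' boundary jitter and label-reassignment noise of per-track severity drawn
#' uniformly from `severity_range`. Tracks therefore span the spectrum from
#' near-perfect to substantial disagreement, which is what corpus-level
#' analyses (quadrants, score distributions, the delta-vs-L relationship)
#' need.
#'
#' @param n_tracks Number of tracks.
#' @param n_annotators Annotations per track.
#' @param duration,depth,boundary_rate,alphabet_size Passed to
#'   [random_hierarchy()].
#' @param severity_range Range of the per-track perturbation severity:
#'   jitter amount in seconds is `4 * s` and relabel probability is `s` for
#'   severity `s`.
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return A list with `corpus` (tibble: `track`, `annotator`, `hierarchy`
#'   list-column) and `base` (list of the unperturbed planted hierarchies,
#'   named by track).
#' @export
synthetic_corpus <- function(n_tracks = 10, n_annotators = 2, duration = 90,
                             depth = 2, boundary_rate = 4, alphabet_size = 5,
                             severity_range = c(0, 0.6), seed = 1) {
  set.seed(seed)
  tracks <- sprintf("track%03d", seq_len(n_tracks))
  base <- list()
  rows <- purrr::map(seq_len(n_tracks), function(i) {
    b <- random_hierarchy(duration, depth, boundary_rate, alphabet_size)
    base[[tracks[i]]] <<- b
    sev <- runif(1, severity_range[1], severity_range[2])
    anns <- purrr::map(seq_len(n_annotators), function(j) {
      g <- perturb_hierarchy(b, "jitter_boundaries", amount = 4 * sev)
      perturb_hierarchy(g, "relabel_noise", amount = sev)
    })
    tibble(track = tracks[i],
           annotator = as.character(seq_len(n_annotators)),
           hierarchy = anns)
  })
  list(corpus = dplyr::bind_rows(rows), base = base)
}
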