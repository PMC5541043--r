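#' Build (and validate) a hierarchical segmentation
#'
#' A hierarchical segmentation is stored as a tibble with one row per
#' segment and columns `level` (integer, 1 = coarsest stored level), `start`,
#' `end` (seconds) and `label` (verbatim, case-sensitive token; `A`, `a` and
#' `A'` are three distinct labels). Within each level the segments must be
#' sorted, non-overlapping and contiguous, starting at 0 and ending at the
#' common track duration. A depth-1 hierarchy is a flat segmentation. Level 0
#' — a single segment spanning the whole track — is never stored but is
#' implied by every hierarchy.
#'
#' Real annotation files carry rounding jitter, so gaps or overlaps between
#' consecutive segments of at most `tolerance` seconds are snapped to the
#' midpoint of the two boundaries; larger ones are validation errors.
#' Per-level track ends within `tolerance` of the hierarchy duration (the
#' maximum segment end) are snapped to it.
#'
#' @param x A data frame with columns `start`, `end`, `label` and optionally
#'   `level` (assumed 1 if absent) and `level_name`.
#' @param tolerance Maximum boundary discrepancy (seconds) repaired by
#'   snapping; default 0.01.
#' @return A validated tibble of class `hierseg_hierarchy`, sorted by level
#'   and start, with levels renumbered consecutively from 1.
#' @examples
#' h <- as_hierarchy(data.frame(
#'   level = c(1, 1, 2, 2, 2),
#'   start = c(0, 10, 0, 5, 10),
#'   end   = c(10, 20, 5, 10, 20),
#'   label = c("A", "B", "a", "b", "c")
#' ))
#' hier_depth(h)
#' hier_duration(h)
#' @export
as_hierarchy <- function(x, tolerance = 0.01) {
  x <- as_tibble(x)
  if (!"level" %in% names(x)) x$level <- 1L
  req <- c("level", "start", "end", "label")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("hierarchy is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("hierarchy has no segments")
  x$label <- as.character(x$label)
  if (any(is.na(x$start) | is.na(x$end) | is.na(x$label))) {
    abort("hierarchy contains missing values")
  }
  if (any(trimws(x$label) == "")) abort("empty segment label")
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    abort(sprintf("segment %d has end <= start (%.6f <= %.6f)",
                  bad, x$end[bad], x$start[bad]))
  }
  # renumber levels consecutively, preserving coarse-to-fine order
  lv <- sort(unique(x$level))
  x$level <- match(x$level, lv)
  x <- dplyr::arrange(x, .data$level, .data$start)
  duration <- max(x$end)

  fixed <- lapply(split(x, x$level), function(seg) {
    n <- nrow(seg)
    if (abs(seg$start[1]) > tolerance) {
      abort(sprintf("level %d starts at %.4f, not 0", seg$level[1], seg$start[1]))
    }
    seg$start[1] <- 0
    if (abs(seg$end[n] - duration) > tolerance) {
      abort(sprintf("level %d ends at %.4f, not the track duration %.4f",
                    seg$level[1], seg$end[n], duration))
    }
    seg$end[n] <- duration
    if (n > 1) {
      gap <- seg$start[-1] - seg$end[-n]
      if (any(abs(gap) > tolerance)) {
        bad <- which(abs(gap) > tolerance)[1]
        abort(sprintf(
          "level %d: %s of %.4f s between segments %d and %d exceeds tolerance",
          seg$level[1], if (gap[bad] > 0) "gap" else "overlap",
          abs(gap[bad]), bad, bad + 1L))
      }
      mid <- (seg$start[-1] + seg$end[-n]) / 2
      seg$start[-1] <- mid
      seg$end[-n] <- mid
    }
    seg
  })
  out <- dplyr::bind_rows(fixed)
  class(out) <- c("hierseg_hierarchy", class(tibble()))
  out
}

#' Duration and depth of a hierarchy
#'
#' @param h A hierarchy tibble (see [as_hierarchy()]).
#' @return `hier_duration()`: the track duration in seconds;
#'   `hier_depth()`: the number of stored levels m.
#' @export
hier_duration <- function(h) max(h$end)

#' @rdname hier_duration
#' @export
hier_depth <- function(h) max(h$level)

#' Read a structural annotation from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`interval_lab`}{whitespace- or tab-separated lines
#'     `start end label`, one file per hierarchy level, passed coarse to
#'     fine.}
#'   \item{`salami_boundary`}{lines `time<TAB>label`; each segment spans from
#'     its own time to the next line's time and the final line marks the
#'     track end (its label, conventionally `End` or `Silence`, is ignored).
#'     Again one file per level.}
#' }
#'
#' @param path Character vector of file paths, one per level, ordered coarse
#'   to fine. Names, if present, become the `level_name` column.
#' @param format `"interval_lab"` (default) or `"salami_boundary"`.
#' @param levels Optional character vector selecting (and ordering) levels by
#'   name; requires `path` to be named. Unselected levels are dropped — e.g.
#'   `levels = c("coarse", "fine")` drops a `function` level.
#' @param tolerance Boundary snapping tolerance passed to [as_hierarchy()].
#' @return A hierarchy tibble (class `hierseg_hierarchy`).
#' @seealso [write_annotation()], [as_hierarchy()]
#' @export
read_annotation <- function(path,
                            format = c("interval_lab", "salami_boundary"),
                            levels = NULL,
                            tolerance = 0.01) {
  format <- match.arg(format)
  if (!is.null(levels)) {
    if (is.null(names(path))) {
      abort("`levels` selection requires named `path`")
    }
    unknown <- setdiff(levels, names(path))
    if (length(unknown) > 0) {
      abort(paste0("unknown level name(s): ", paste(unknown, collapse = ", ")))
    }
    path <- path[levels]
  }
  missing_files <- path[!file.exists(path)]
  if (length(missing_files) > 0) {
    abort(paste0("annotation file not found: ", missing_files[1]))
  }
  parse_one <- switch(format,
    interval_lab = parse_interval_lab,
    salami_boundary = parse_salami_boundary
  )
  segs <- purrr::imap(
    setNames(as.list(path), names(path) %||% seq_along(path)),
    function(p, nm) {
      seg <- parse_one(p)
      if (nrow(seg) == 0) abort(paste0("empty annotation level: ", p))
      seg$level_name <- as.character(nm)
      seg
    }
  )
  out <- dplyr::bind_rows(segs, .id = NULL)
  out$level <- rep(seq_along(segs), vapply(segs, nrow, integer(1)))
  as_hierarchy(out, tolerance = tolerance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_interval_lab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 3)
  if (length(bad) > 0) {
    abort(sprintf("%s:%d: expected 'start end label', got '%s'",
                  path, keep[bad[1]], lines[keep[bad[1]]]))
  }
  start <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1)))
  end <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("%s:%d: non-numeric interval bound", path, keep[bad]))
  }
  label <- vapply(toks, function(tk) paste(tk[-(1:2)], collapse = " "), "")
  tibble(start = start, end = end, label = label)
}

parse_salami_boundary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  toks <- strsplit(lines[keep], "\t")
  time <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1)))
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    abort(sprintf("%s:%d: non-numeric boundary time", path, keep[bad]))
  }
  if (length(time) < 2) {
    abort(paste0(path, ": a boundary annotation needs at least two lines"))
  }
  label <- vapply(toks, function(tk) {
    if (length(tk) >= 2) trimws(tk[[2]]) else ""
  }, "")
  n <- length(time)
  if (any(label[-n] == "")) {
    bad <- which(label[-n] == "")[1]
    abort(sprintf("%s:%d: missing segment label", path, keep[bad]))
  }
  tibble(start = time[-n], end = time[-1], label = label[-n])
}

#' Write a hierarchy to interval LAB files
#'
#' Writes one `start end label` file per level with boundaries printed to six
#' decimal places, so that `read_annotation()` round-trips boundaries to
#' 1e-6 s and labels exactly.
#'
#' @param h A hierarchy tibble.
#' @param path Character vector of output file paths, one per level
#'   (coarse to fine).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(h, path) {
  h <- as_hierarchy(h)
  m <- hier_depth(h)
  if (length(path) != m) {
    abort(sprintf("need %d output paths (one per level), got %d", m, length(path)))
  }
  for (k in seq_len(m)) {
    seg <- h[h$level == k, ]
    writeLines(sprintf("%.6f\t%.6f\t%s", seg$start, seg$end, seg$label), path[k])
  }
  invisible(path)
}

#' Sample a hierarchy's labels on a uniform frame grid
#'
#' Converts interval annotations to per-level integer label sequences on a
#' uniform grid of `ceiling(duration * frame_rate)` frames, frame i
#' (0-based) taking the label of the segment containing time `i / frame_rate`
#' under the half-open `[start, end)` convention: a boundary instant belongs
#' to the segment to its right. Integer codes are level-local; no cross-level
#' label identity is implied.
#'
#' @param h A hierarchy tibble.
#' @param frame_rate Sampling rate in Hz; 10 Hz is the conventional rate for
#'   the structural metrics, 4 Hz for the acoustic correlation pipeline.
#' @return An integer matrix of class `hierseg_grid` with one row per level
#'   and one column per frame; attribute `frame_rate` records the rate.
#' @examples
#' h <- as_hierarchy(data.frame(start = c(0, 0.25), end = c(0.25, 0.6),
#'                              label = c("A", "B")))
#' sample_labels(h, frame_rate = 10)
#' @export
sample_labels <- function(h, frame_rate = 10) {
  h <- as_hierarchy(h)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort("`frame_rate` must be a positive number")
  }
  duration <- hier_duration(h)
  n <- as.integer(ceiling(duration * frame_rate - 1e-9))
  t <- (seq_len(n) - 1) / frame_rate
  m <- hier_depth(h)
  labs <- matrix(0L, nrow = m, ncol = n)
  for (k in seq_len(m)) {
    seg <- h[h$level == k, ]
    idx <- findInterval(t, seg$start)
    idx[idx < 1] <- 1L             # guard against negative rounding noise
    idx[idx > nrow(seg)] <- nrow(seg)
    lab_seq <- seg$label[idx]
    labs[k, ] <- match(lab_seq, unique(lab_seq))
  }
  frame_grid(labs, frame_rate)
}

#' Construct a frame-label grid directly
#'
#' Mostly useful for tests and worked examples: wraps a per-level label
#' matrix (rows = levels coarse to fine, columns = frames; any atomic type)
#' into the grid object that [meet_matrix()] consumes. Labels are recoded to
#' level-local integers, which preserves the only structure the metrics use —
#' within-level equality.
#'
#' @param x A matrix (levels x frames), or a list/vector of equal-length
#'   per-level label vectors.
#' @param frame_rate Frame rate in Hz attached as an attribute.
#' @return An integer matrix of class `hierseg_grid`.
#' @examples
#' frame_grid(rbind(c("A", "A", "B", "B"), c("a", "b", "c", "c")))
#' @export
frame_grid <- function(x, frame_rate = 10) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) abort("all level sequences must have equal length")
    x <- do.call(rbind, x)
  }
  if (is.atomic(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.matrix(x)) abort("`x` must be a matrix or list of label vectors")
  coded <- t(apply(x, 1, function(r) match(r, unique(r))))
  if (ncol(x) == 1) coded <- matrix(coded, nrow = nrow(x))
  storage.mode(coded) <- "integer"
  structure(coded, class = "hierseg_grid", frame_rate = frame_rate)
}

#' @export
print.hierseg_grid <- function(x, ...) {
  cat(sprintf("<hierseg_grid> %d level(s) x %d frames @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "frame_rate")))
  print(unclass(x)[, seq_len(min(ncol(x), 20)), drop = FALSE])
  if (ncol(x) > 20) cat("...\n")
  invisible(x)
}

#' Sample two annotations of one recording on a common frame grid
#'
#' Annotations of the same recording often disagree slightly about the track
#' duration. Both hierarchies are sampled over `[0, min(duration1,
#' duration2))`; a warning is issued when the durations differ by more than
#' `tolerance`, and an error when the longer exceeds the shorter by more than
#' a factor of `fail_ratio` (such a mismatch suggests the annotations do not
#' describe the same recording). Truncation, never label fill, is used so
#' that no agreement is fabricated.
#'
#' @param h_ref,h_est Hierarchy tibbles for the same recording.
#' @param frame_rate Sampling rate in Hz.
#' @param tolerance Duration discrepancy (seconds) tolerated silently.
#' @param fail_ratio Hard-failure multiple for the duration ratio.
#' @return A list with grids `ref` and `est` of identical dimensions
#'   (`hierseg_grid` objects).
#' @export
align_pair <- function(h_ref, h_est, frame_rate = 10, tolerance = 1,
                       fail_ratio = 2) {
  h_ref <- as_hierarchy(h_ref)
  h_est <- as_hierarchy(h_est)
  d1 <- hier_duration(h_ref)
  d2 <- hier_duration(h_est)
  if (max(d1, d2) / min(d1, d2) > fail_ratio) {
    abort(sprintf(
      "annotation durations %.2f s and %.2f s differ by more than %gx",
      d1, d2, fail_ratio))
  }
  if (abs(d1 - d2) > tolerance) {
    warn(sprintf(
      "annotation durations differ by %.2f s (%.2f vs %.2f); truncating to the shorter",
      abs(d1 - d2), d1, d2))
  }
  dmin <- min(d1, d2)
  truncate_to <- function(h, d) {
    h <- h[h$start < d, ]
    h$end <- pmin(h$end, d)
    h
  }
  list(
    ref = sample_labels(truncate_to(h_ref, dmin), frame_rate),
    est = sample_labels(truncate_to(h_est, dmin), frame_rate)
  )
}
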