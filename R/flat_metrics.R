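#' Frame-pairwise classification scores between two flat label sequences
#'
#' Each flat labeling of `T` frames induces the set `A(S)` of unordered pairs
#' of distinct frames that carry the same label. Pairwise precision is the
#' fraction of the estimate's pairs found in the reference,
#' `|A(ref) ∩ A(est)| / |A(est)|`; pairwise recall is the same intersection
#' over `|A(ref)|`; `f` is their harmonic mean. The counts are obtained from
#' the joint label contingency table (sums of `choose(n, 2)`), never by
#' materializing pair sets, so the cost is linear in `T`.
#'
#' Swapping the arguments exchanges precision and recall. A sequence with
#' all-distinct labels induces no pairs; the affected score is defined as 0,
#' with a warning.
#'
#' @param ref,est Equal-length label vectors (any atomic type), one entry per
#'   frame, or 1-level `hierseg_grid` objects.
#' @return A one-row tibble with columns `precision`, `recall`, `f`.
#' @examples
#' pairwise_scores(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
pairwise_scores <- function(ref, est) {
  ref <- flat_labels(ref)
  est <- flat_labels(est)
  if (length(ref) != length(est)) {
    abort(sprintf("sequence lengths differ: %d vs %d", length(ref), length(est)))
  }
  if (length(ref) < 2) abort("need at least 2 frames for pairwise scores")
  n_pairs <- function(counts) sum(choose(counts, 2))
  joint <- table(ref, est)
  inter <- n_pairs(joint)
  size_ref <- n_pairs(rowSums(joint))
  size_est <- n_pairs(colSums(joint))
  if (size_est == 0) warn("estimate has no similarly-labeled pairs; precision set to 0")
  if (size_ref == 0) warn("reference has no similarly-labeled pairs; recall set to 0")
  p <- if (size_est > 0) inter / size_est else 0
  r <- if (size_ref > 0) inter / size_ref else 0
  tibble(precision = p, recall = r, f = f_measure(p, r))
}

#' Normalized conditional entropy scores between two flat label sequences
#'
#' Treats the co-occurring frame labels as a sample from a joint distribution
#' `P[y_ref, y_est]` and scores how well one labeling predicts the other. The
#' over-segmentation score is `1 - H(est | ref) / log |Y_est|` (reported in
#' the `precision` column: a high value means the estimate is not
#' over-segmented relative to the reference), and the under-segmentation
#' score is `1 - H(ref | est) / log |Y_ref|` (the `recall` column); `f` is
#' their harmonic mean. Scores are clipped to `[0, 1]` and are invariant to
#' the logarithm base, since numerator and normalizer scale together.
#'
#' When a label set is a singleton the corresponding normalized entropy is
#' taken as 0, i.e. the score is 1: a one-label estimate cannot be
#' over-segmented.
#'
#' @inheritParams pairwise_scores
#' @return A one-row tibble with columns `precision` (over-segmentation
#'   score), `recall` (under-segmentation score) and `f`.
#' @examples
#' nce_scores(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
nce_scores <- function(ref, est) {
  ref <- flat_labels(ref)
  est <- flat_labels(est)
  if (length(ref) != length(est)) {
    abort(sprintf("sequence lengths differ: %d vs %d", length(ref), length(est)))
  }
  if (length(ref) < 1) abort("need at least 1 frame for NCE scores")
  joint <- table(ref, est) / length(ref)
  p_ref <- rowSums(joint)
  p_est <- colSums(joint)
  # H(B | A) from the joint table with A on rows
  cond_entropy <- function(joint, p_row) {
    nz <- joint > 0
    sum(joint[nz] * log(rep(p_row, times = ncol(joint))[nz] / joint[nz]))
  }
  norm_term <- function(h, k) if (k > 1) h / log(k) else 0
  over <- 1 - norm_term(cond_entropy(joint, p_ref), length(p_est))
  under <- 1 - norm_term(cond_entropy(t(joint), p_est), length(p_ref))
  over <- min(max(over, 0), 1)
  under <- min(max(under, 0), 1)
  tibble(precision = over, recall = under, f = f_measure(over, under))
}

# accept label vectors, factors, or a single-level grid
flat_labels <- function(x) {
  if (inherits(x, "hierseg_grid")) {
    if (nrow(x) != 1) {
      abort("flat metrics need a single-level grid; subset one level first")
    }
    return(as.vector(unclass(x)[1, ]))
  }
  if (is.matrix(x)) {
    if (nrow(x) != 1) abort("flat metrics need a single label sequence")
    return(as.vector(x))
  }
  if (!is.atomic(x)) abort("labels must be an atomic vector")
  as.vector(x)
}
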