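# Independent brute-force oracles, deliberately naive: they enumerate the
# defining sets instead of using contingency/histogram arithmetic.

# pairwise precision/recall by enumerating all unordered pairs of frames
brute_pairwise <- function(ref, est) {
  n <- length(ref)
  pairs_ref <- character(0)
  pairs_est <- character(0)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      key <- paste(u, v)
      if (ref[u] == ref[v]) pairs_ref <- c(pairs_ref, key)
      if (est[u] == est[v]) pairs_est <- c(pairs_est, key)
    }
  }
  inter <- length(intersect(pairs_ref, pairs_est))
  p <- if (length(pairs_est) > 0) inter / length(pairs_est) else 0
  r <- if (length(pairs_ref) > 0) inter / length(pairs_ref) else 0
  c(precision = p, recall = r)
}

# comparison-triple counts by enumerating all ordered triples of distinct
# frames (vectorized over the full T^3 grid, but still O(T^3))
brute_triple_counts <- function(m_ref, m_est) {
  n <- nrow(m_ref)
  g <- expand.grid(t = seq_len(n), u = seq_len(n), v = seq_len(n))
  g <- g[g$t != g$u & g$t != g$v & g$u != g$v, ]
  in_ref <- m_ref[cbind(g$t, g$u)] > m_ref[cbind(g$t, g$v)]
  in_est <- m_est[cbind(g$t, g$u)] > m_est[cbind(g$t, g$v)]
  list(size_ref = sum(in_ref), size_est = sum(in_est),
       intersection = sum(in_ref & in_est))
}

# meet matrix by looping over every pair and level
brute_meet <- function(grid) {
  g <- unclass(grid)
  n <- ncol(g)
  M <- matrix(0L, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      deepest <- 0L
      for (k in seq_len(nrow(g))) {
        if (g[k, u] == g[k, v]) deepest <- k
      }
      M[u, v] <- deepest
    }
  }
  M
}

# random frame-label grid for property tests
rand_grid <- function(n_frames, depth, alphabet = 4, frame_rate = 10) {
  labs <- matrix(sample.int(alphabet, n_frames * depth, replace = TRUE),
                 nrow = depth)
  frame_grid(labs, frame_rate)
}

# hierarchy with uniform 0.1 s segments encoding the given per-level frame
# labels at 10 Hz (one frame per segment)
hier_from_codes <- function(...) {
  levels <- list(...)
  segs <- lapply(seq_along(levels), function(k) {
    lab <- levels[[k]]
    data.frame(level = k,
               start = (seq_along(lab) - 1) / 10,
               end = seq_along(lab) / 10,
               label = as.character(lab))
  })
  as_hierarchy(do.call(rbind, segs))
}

write_lab <- function(segs, path = tempfile(fileext = ".lab")) {
  writeLines(sprintf("%g %g %s", segs$start, segs$end, segs$label), path)
  path
}

# a hierarchy whose meet matrix has off-diagonal contrast at the given frame
# rates, i.e. whose comparison set is non-empty: the precondition for the
# "scores equal 1" invariances (degenerate single-label annotations score 0
# by convention even against themselves). Draws from the ambient RNG.
has_contrast <- function(h, frame_rate) {
  M <- meet_matrix(sample_labels(h, frame_rate))
  od <- M[row(M) != col(M)]
  length(unique(od)) > 1
}

draw_structured <- function(duration, depth = 2, boundary_rate = 4,
                            alphabet_size = 5, rates = c(4, 10)) {
  repeat {
    h <- random_hierarchy(duration, depth, boundary_rate, alphabet_size)
    if (all(vapply(rates, function(r) has_contrast(h, r), logical(1)))) {
      return(h)
    }
  }
}
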