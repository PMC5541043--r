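sr <- 22050

click_track <- function(bpm, dur = 6, sr = 22050) {
  y <- numeric(round(dur * sr))
  onsets <- seq(0, dur - 0.05, by = 60 / bpm)
  burst <- sin(2 * pi * 1000 * (0:80) / sr) * exp(-(0:80) / 20)
  for (s in round(onsets * sr) + 1) {
    j <- s:min(s + 80, length(y))
    y[j] <- y[j] + burst[seq_along(j)]
  }
  y
}

test_that("feature extractors produce the documented dimensions", {
  set.seed(31)
  y <- rnorm(sr * 3) * 0.1
  expect_equal(nrow(tempo_features(y)), 384)
  expect_equal(nrow(rhythm_features(tempo_features(y))), 33)
  expect_equal(nrow(chroma_features(y)), 12)
  expect_equal(nrow(mfcc_features(y)), 20)
  expect_error(tempo_features(numeric(0)), "non-empty")
  expect_error(rhythm_features(matrix(0, 10, 5)), "384 rows")
})

test_that("silence gives all-zero tempo columns with no normalization applied", {
  xt <- tempo_features(numeric(sr * 2))
  expect_true(all(unclass(xt) == 0))
})

test_that("a 120-BPM click track shows an autocorrelation peak near lag 21-22", {
  xt <- tempo_features(click_track(120))
  ac <- rowMeans(unclass(xt))
  # the 0.5 s inter-click interval is 21.5 frames at ~43 Hz
  peak <- which.max(ac[11:33]) + 10 - 1   # lag index (0-based), away from lag 0
  expect_true(peak %in% 20:23)
  expect_true(all(unclass(xt) >= 0))
  expect_lte(max(unclass(xt)), 1)
})

test_that("rhythm features are closer across tempi than to noise", {
  x100 <- rowMeans(unclass(rhythm_features(tempo_features(click_track(100)))))
  x150 <- rowMeans(unclass(rhythm_features(tempo_features(click_track(150)))))
  set.seed(32)
  xn <- rowMeans(unclass(rhythm_features(tempo_features(rnorm(sr * 6) * 0.1))))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(x100, x150), cosine(x100, xn))
  expect_gt(cosine(x100, x150), cosine(x150, xn))
})

test_that("rhythm features stay finite on silent input", {
  xr <- rhythm_features(tempo_features(numeric(sr * 2)))
  expect_true(all(is.finite(unclass(xr))))
})

test_that("chroma of a 440 Hz sine peaks at pitch class A with unit maximum", {
  y <- sin(2 * pi * 440 * seq(0, 2, by = 1 / sr))
  xc <- unclass(chroma_features(y))
  interior <- xc[, 20:60]
  expect_equal(unname(which.max(rowMeans(interior))), 10)  # row 10 = A (C = 1)
  expect_equal(unname(apply(interior, 2, max)), rep(1, ncol(interior)))
})

test_that("MFCCs are constant on constant input and discriminate timbres", {
  xm <- unclass(mfcc_features(rep(0.5, sr * 2)))
  interior <- xm[, 20:60]
  expect_equal(max(apply(interior, 1, stats::sd)), 0)
  y <- sin(2 * pi * 220 * seq(0, 2, by = 1 / sr))
  set.seed(33)
  noise <- rnorm(sr * 2) * 0.1
  xs <- unclass(mfcc_features(y))
  xn <- unclass(mfcc_features(noise))
  d <- rowMeans(xs[, 20:60]) - rowMeans(xn[, 20:60])
  expect_gt(sqrt(sum(d[-1]^2)), 1)   # differ beyond coefficient 0
})

test_that("prepare_features resamples to 4 Hz and embeds chroma/MFCC", {
  set.seed(34)
  y <- rnorm(sr * 5) * 0.1
  feats <- list(tempo_features(y), rhythm_features(tempo_features(y)),
                chroma_features(y), mfcc_features(y))
  prep <- prepare_features(feats)
  expect_equal(vapply(prep, nrow, integer(1)),
               c(tempo = 384L, rhythm = 33L, chroma = 36L, mfcc = 60L))
  n_cols <- vapply(prep, ncol, integer(1))
  expect_equal(length(unique(n_cols)), 1L)
  duration <- ncol(feats[[1]]) / attr(feats[[1]], "frame_rate")
  expect_equal(unname(n_cols[1]), as.integer(ceiling(duration * 4 - 1e-9)))
  # constant features stay constant through interpolation and embedding
  const <- hierseg:::new_features(matrix(3, 12, 40), "chroma", 43.07)
  pc <- prepare_features(list(const))$chroma
  expect_true(all(unclass(pc) == 3))
  expect_equal(nrow(pc), 36)
})

test_that("self-similarity matches the closed form on two-block features", {
  a <- c(1, 0, 0)
  b <- c(0, 2, 0)
  x <- cbind(a, a, b, b)
  G <- self_similarity(x)
  expect_true(isSymmetric(unname(unclass(G))))
  expect_equal(unname(diag(unclass(G))), rep(1, 4))
  # squared cross-block distance is 5; each row's median of {0, 0, 5, 5}
  # (self included) is 2.5, so sigma = 2.5
  expect_equal(attr(G, "bandwidth"), 2.5)
  expect_equal(G[1, 3], exp(-5 / 2.5))
  expect_equal(G[1, 2], 1)
  # scale invariance: scaling features scales sigma, G unchanged
  G2 <- self_similarity(10 * x)
  expect_equal(attr(G2, "bandwidth"), 250)
  expect_equal(unclass(G2), unclass(G), ignore_attr = TRUE)
  expect_error(self_similarity(cbind(a, a, a)), "identical")
})

test_that("matrix normalization is exact, affine-invariant and idempotent", {
  m <- diag(2)
  expect_equal(normalize_matrix(m),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  set.seed(35)
  d <- matrix(rnorm(36), 6)
  nd <- normalize_matrix(d)
  expect_equal(mean(nd), 0)
  expect_equal(sqrt(sum(nd^2)), 1)
  expect_equal(normalize_matrix(3 * d + 7), nd)
  expect_equal(normalize_matrix(nd), nd)
  expect_error(normalize_matrix(matrix(2, 3, 3)), "constant")
})

test_that("correlation vectors are unit for self and bounded by 1", {
  set.seed(36)
  h <- draw_structured(duration = 30)
  m <- meet_matrix(sample_labels(h, 4))
  ssms <- lapply(planted_features(h), self_similarity)
  z <- correlation_vector(m, ssms)
  expect_equal(z$feature, c("tempo", "rhythm", "chroma", "mfcc"))
  expect_true(all(abs(z$z) <= 1 + 1e-12))
  # correlation of the meet matrix with itself is exactly 1
  self_z <- sum(normalize_matrix(m) * normalize_matrix(m))
  expect_equal(self_z, 1)
})

test_that("annotation distance is zero for self, symmetric, non-negative", {
  set.seed(38)
  h1 <- draw_structured(duration = 30)
  h2 <- perturb_hierarchy(h1, "relabel_noise", amount = 0.4)
  while (!has_contrast(h2, 4)) {
    h2 <- perturb_hierarchy(h1, "relabel_noise", amount = 0.4)
  }
  ssms <- lapply(planted_features(h1), self_similarity)
  m1 <- meet_matrix(sample_labels(h1, 4))
  m2 <- meet_matrix(sample_labels(h2, 4))
  expect_equal(annotation_distance(m1, m1, ssms)$delta, 0)
  d12 <- annotation_distance(m1, m2, ssms)
  d21 <- annotation_distance(m2, m1, ssms)
  expect_equal(d12$delta, d21$delta)
  expect_gte(d12$delta, 0)
  expect_s3_class(tidy(d12), "tbl_df")
  expect_equal(nrow(tidy(d12)), 8)
  expect_equal(glance(d12)$delta, d12$delta)
})

test_that("with orthonormal similarity matrices delta is the squared z-distance", {
  # zero-mean matrices with disjoint supports: normalization leaves them
  # mutually orthogonal, so W is the identity
  n <- 6
  mk <- function(p1, p2) {
    d <- matrix(0, n, n)
    d[p1[1], p1[2]] <- d[p1[2], p1[1]] <- 1
    d[p2[1], p2[2]] <- d[p2[2], p2[1]] <- -1
    d
  }
  ssms <- list(tempo = mk(c(1, 2), c(3, 4)), rhythm = mk(c(1, 3), c(2, 4)),
               chroma = mk(c(1, 4), c(2, 3)), mfcc = mk(c(1, 5), c(2, 6)))
  m1 <- meet_matrix(rand_grid(n, 2))
  m2 <- meet_matrix(rand_grid(n, 3))
  d <- annotation_distance(m1, m2, ssms)
  expect_equal(unclass(d$w), diag(4), ignore_attr = TRUE)
  z1 <- correlation_vector(m1, ssms)$z
  z2 <- correlation_vector(m2, ssms)$z
  expect_equal(d$delta, sum((z1 - z2)^2))
})

test_that("a singular Gram matrix falls back to the pseudo-inverse", {
  set.seed(41)
  h <- draw_structured(duration = 20)
  ssm <- self_similarity(planted_features(h)$tempo)
  ssms <- list(tempo = ssm, rhythm = ssm, chroma = ssm, mfcc = ssm)
  m1 <- meet_matrix(sample_labels(h, 4))
  h2 <- perturb_hierarchy(h, "relabel_noise", amount = 0.5)
  while (!has_contrast(h2, 4)) {
    h2 <- perturb_hierarchy(h, "relabel_noise", amount = 0.5)
  }
  m2 <- meet_matrix(sample_labels(h2, 4))
  expect_message(d <- annotation_distance(m1, m2, ssms), "pseudo-inverse")
  expect_true(is.finite(d$delta))
  expect_gte(d$delta, 0)
})
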