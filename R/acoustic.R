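#' @section Acoustic features:
#' The four descriptors follow the common music-structure toolchain: all are
#' derived from a 22,050 Hz mono waveform with a hop of 512 samples
#' (~43 Hz frame rate). Tempo features are windowed autocorrelations of the
#' onset strength envelope; rhythm features are their scale-transform
#' magnitudes (approximately tempo-invariant); chroma features fold a
#' log-frequency spectrum into 12 pitch classes; timbre is summarized by
#' MFCCs.
#' @name acoustic-features
NULL

AUDIO_SR <- 22050L
HOP <- 512L

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

check_audio <- function(audio) {
  if (!is.numeric(audio) || length(audio) == 0) {
    abort("`audio` must be a non-empty numeric waveform (22,050 Hz mono)")
  }
  if (any(!is.finite(audio))) abort("`audio` contains non-finite samples")
  as.numeric(audio)
}

# power spectrogram, centered frames: column j covers time (j-1)*hop/sr
stft_power <- function(y, n_fft = 2048, hop = HOP) {
  if (length(y) < hop) abort("signal shorter than one hop (512 samples)")
  pad <- n_fft %/% 2
  yp <- c(numeric(pad), y, numeric(pad))
  n_frames <- 1 + (length(y) %/% hop)
  need <- (n_frames - 1) * hop + n_fft
  if (length(yp) < need) yp <- c(yp, numeric(need - length(yp)))
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1) * hop, "+")
  frames <- matrix(yp[idx], nrow = n_fft) * hann_window(n_fft)
  spec <- stats::mvfft(frames)
  Mod(spec[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2
}

# Slaney-style mel scale and triangular filterbank
hz_to_mel <- function(f) {
  m <- f / (200 / 3)
  hi <- f >= 1000
  m[hi] <- 15 + log(f[hi] / 1000) / (log(6.4) / 27)
  m
}

mel_to_hz <- function(m) {
  f <- m * (200 / 3)
  hi <- m >= 15
  f[hi] <- 1000 * exp((m[hi] - 15) * log(6.4) / 27)
  f
}

mel_filterbank <- function(n_mels = 128, n_fft = 2048, sr = AUDIO_SR,
                           fmax = sr / 2) {
  freqs <- (seq_len(n_fft %/% 2 + 1) - 1) * sr / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(freqs))
  for (k in seq_len(n_mels)) {
    lo <- pts[k]; ctr <- pts[k + 1]; hi <- pts[k + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[k, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)  # area normalization
  }
  fb
}

power_to_db <- function(x, floor = 1e-10) 10 * log10(pmax(x, floor))

log_mel_spectrogram <- function(audio, sr = AUDIO_SR, n_mels = 128) {
  P <- stft_power(check_audio(audio))
  power_to_db(mel_filterbank(n_mels, 2048, sr) %*% P)
}

# band-averaged half-wave-rectified first difference of the log-power mel
# spectrogram; first frame has no predecessor and gets 0
onset_strength <- function(audio, sr = AUDIO_SR) {
  S <- log_mel_spectrogram(audio, sr)
  flux <- cbind(0, pmax(S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE], 0))
  colMeans(flux)
}

new_features <- function(values, kind, frame_rate) {
  structure(values, class = "hierseg_features", kind = kind,
            frame_rate = frame_rate)
}

#' @export
print.hierseg_features <- function(x, ...) {
  cat(sprintf("<hierseg_features: %s> %d x %d @ %.3f Hz\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "frame_rate")))
  invisible(x)
}

#' Tempo features: short-time autocorrelation of the onset envelope
#'
#' The onset strength envelope is the band-averaged half-wave-rectified
#' first difference of a log-power 128-band mel spectrogram (hop 512 at
#' 22,050 Hz, ~43 Hz frame rate, bands up to 11,025 Hz). Around every frame a
#' centered, Hann-windowed 384-frame excerpt of the envelope (~8.9 s) is
#' autocorrelated over lags 0..383; peaks at lag `l` indicate onsets
#' recurring every `l` frames, i.e. the local tempo. Each column is
#' normalized by its peak amplitude; all-zero columns (silence) are left as
#' zeros. The envelope is zero-padded at the edges so windows are always
#' complete.
#'
#' @param audio Numeric mono waveform sampled at 22,050 Hz.
#' @param sr Sample rate of `audio` in Hz.
#' @return A 384 x T feature matrix (class `hierseg_features`, kind
#'   `"tempo"`) on the ~43 Hz frame grid.
#' @export
tempo_features <- function(audio, sr = AUDIO_SR) {
  env <- onset_strength(audio, sr)
  win <- 384L
  n <- length(env)
  padded <- c(numeric(win / 2), env, numeric(win / 2))
  idx <- outer(seq_len(win) - win / 2 - 1, seq_len(n) + win / 2, "+")
  seg <- matrix(padded[idx], nrow = win) * hann_window(win)
  # circular FFT autocorrelation, zero-padded to >= 2*win to make it linear
  Z <- rbind(seg, matrix(0, win * 2, n))
  S <- Mod(stats::mvfft(Z))^2
  R <- Re(stats::mvfft(S, inverse = TRUE)) / nrow(Z)
  X <- pmax(R[seq_len(win), , drop = FALSE], 0)  # clamp FFT roundoff
  peaks <- apply(X, 2, max)
  pos <- peaks > 0
  X[, pos] <- sweep(X[, pos, drop = FALSE], 2, peaks[pos], "/")
  new_features(pmin(X, 1), "tempo", sr / HOP)
}

#' Rhythm features: scale-transform magnitude of the tempo features
#'
#' Playing the same rhythmic pattern faster rescales the lag axis of its
#' onset autocorrelation multiplicatively. Resampling each tempo-feature
#' column on a logarithmic lag axis turns that rescaling into a shift, and
#' taking the Fourier magnitude over the log-lag axis discards the shift —
#' yielding an approximately tempo-invariant rhythm descriptor (the scale,
#' or Mellin, transform magnitude).
#'
#' Columns are linearly interpolated onto a geometric grid of 512 points
#' from a minimum lag `t0 = 0.5` frames to the window length of 384 frames,
#' weighted by the square root of the lag (the measure factor `e^(u/2)` of
#' the exponentially resampled Mellin integral, which makes the transform
#' magnitude scale-invariant rather than merely shift-sensitive), Fourier
#' transformed with `n = 64` scale bins, the conjugate-symmetric negative
#' bins discarded (`floor(n/2) + 1 = 33` rows), and the log-power of the
#' magnitude taken (floored at 1e-10 so silent columns stay finite). The
#' scale meaning of bin `k` depends only on the total log-lag range, not on
#' the grid density, so the grid size affects aliasing error only.
#'
#' @param x_tau A 384-row tempo feature matrix from [tempo_features()].
#' @param t0 Minimum lag in fractional frames.
#' @param n_scale Number of scale bins.
#' @return A 33 x T feature matrix (kind `"rhythm"`).
#' @export
rhythm_features <- function(x_tau, t0 = 0.5, n_scale = 64) {
  if (nrow(x_tau) != 384) {
    abort(sprintf("tempo features must have 384 rows, got %d", nrow(x_tau)))
  }
  n_out <- n_scale %/% 2 + 1
  n_grid <- 512  # power of two >= 2 * n_scale; denser = less aliasing
  lag_max <- nrow(x_tau)
  grid <- t0 * (lag_max / t0)^((seq_len(n_grid) - 1) / (n_grid - 1))
  lags <- seq_len(nrow(x_tau)) - 1
  res <- apply(unclass(x_tau), 2, function(col) {
    approx(lags, col, xout = grid, rule = 2)$y
  })
  if (is.null(dim(res))) res <- matrix(res, nrow = n_grid)
  res <- res * sqrt(grid)   # Mellin measure factor e^(u/2)
  mag <- Mod(stats::mvfft(res))[seq_len(n_out), , drop = FALSE]
  new_features(power_to_db(mag^2), "rhythm", attr(x_tau, "frame_rate"))
}

#' Chroma features: pitch-class energy profiles
#'
#' Spectral energy is aggregated on a log-frequency axis of 36 bins per
#' octave spanning C1 (32.70 Hz) to C8, summed within the 12 pitch classes,
#' and each frame is normalized by its peak amplitude (all-zero frames are
#' left as zeros). The log-frequency aggregation is implemented as a
#' filterbank over a 4096-point STFT on the same ~43 Hz frame grid as the
#' other features.
#'
#' @inheritParams tempo_features
#' @return A 12 x T feature matrix (kind `"chroma"`); row 1 is pitch class C.
#' @export
chroma_features <- function(audio, sr = AUDIO_SR) {
  n_fft <- 4096
  P <- stft_power(check_audio(audio), n_fft = n_fft)
  freqs <- (seq_len(nrow(P)) - 1) * sr / n_fft
  f_c1 <- 32.70320
  q <- 36 * log2(freqs / f_c1)          # fractional log-frequency bin
  keep <- is.finite(q) & q >= -0.5 & q <= 251.5   # C1 .. C8 range
  pc <- (round(q[keep] / 3)) %% 12      # 3 bins per semitone
  X <- rowsum(P[keep, , drop = FALSE], group = pc)
  full <- matrix(0, 12, ncol(P))
  full[as.integer(rownames(X)) + 1, ] <- X
  peaks <- apply(full, 2, max)
  pos <- peaks > 0
  full[, pos] <- sweep(full[, pos, drop = FALSE], 2, peaks[pos], "/")
  new_features(full, "chroma", sr / HOP)
}

#' Timbre features: mel-frequency cepstral coefficients
#'
#' The first 20 MFCCs of the same log-power 128-band mel spectrogram used by
#' the tempo features (orthonormal DCT-II over the mel axis), on the ~43 Hz
#' frame grid.
#'
#' @inheritParams tempo_features
#' @param n_mfcc Number of cepstral coefficients.
#' @return A 20 x T feature matrix (kind `"mfcc"`).
#' @export
mfcc_features <- function(audio, sr = AUDIO_SR, n_mfcc = 20) {
  S <- log_mel_spectrogram(audio, sr)
  N <- nrow(S)
  k <- seq_len(n_mfcc) - 1
  D <- sqrt(2 / N) * cos(pi * outer(k, seq_len(N) - 0.5) / N)
  D[1, ] <- D[1, ] / sqrt(2)
  new_features(D %*% S, "mfcc", sr / HOP)
}

#' Down-sample features to a common 4 Hz grid and add local context
#'
#' Self-similarity matrices at the native ~43 Hz frame rate would be
#' enormous, so all feature matrices are linearly interpolated onto a shared
#' 4 Hz grid covering the common duration. Chroma and MFCC frames describe
#' only a short analysis window, so after down-sampling each of their frames
#' is extended by time-delay embedding — concatenating the two previous
#' frames (the first frame repeated as padding) — giving 36 and 60 rows
#' respectively. Tempo and rhythm features already summarize ~8.9 s of
#' context and are not embedded.
#'
#' @param features Named list of `hierseg_features` (any subset of tempo,
#'   rhythm, chroma, mfcc).
#' @param frame_rate Target frame rate in Hz.
#' @return A named list of `hierseg_features` at `frame_rate`, all with the
#'   same number of columns `ceiling(duration * frame_rate)`.
#' @export
prepare_features <- function(features, frame_rate = 4) {
  if (is.null(names(features))) {
    names(features) <- vapply(features, function(f) attr(f, "kind"), "")
  }
  duration <- min(vapply(features, function(f) {
    ncol(f) / attr(f, "frame_rate")
  }, numeric(1)))
  n_out <- as.integer(ceiling(duration * frame_rate - 1e-9))
  t_out <- (seq_len(n_out) - 1) / frame_rate
  purrr::map(features, function(f) {
    fr <- attr(f, "frame_rate")
    kind <- attr(f, "kind")
    t_in <- (seq_len(ncol(f)) - 1) / fr
    v <- unclass(f)
    out <- t(apply(v, 1, function(row) approx(t_in, row, xout = t_out, rule = 2)$y))
    if (identical(kind, "chroma") || identical(kind, "mfcc")) {
      lag1 <- out[, c(1, seq_len(n_out - 1)), drop = FALSE]
      lag2 <- lag1[, c(1, seq_len(n_out - 1)), drop = FALSE]
      out <- rbind(out, lag1, lag2)
    }
    new_features(out, kind, frame_rate)
  })
}

#' Gaussian-kernel self-similarity matrix of a feature matrix
#'
#' `G[u, v] = exp(-||X[u] - X[v]||^2 / sigma)` where `X[t]` is the feature
#' column at frame `t` and the bandwidth `sigma` is the mean over frames `u`
#' of the median over `v` of the squared distances. The construction is
#' invariant to a global rescaling of the features, since `sigma` scales with
#' the squared distances.
#'
#' @param x A feature matrix (columns = frames), e.g. from
#'   [prepare_features()] or [planted_features()].
#' @return A `T x T` matrix of class `hierseg_ssm` with unit diagonal,
#'   entries in `(0, 1]`, and attributes `bandwidth`, `kind`, `frame_rate`.
#' @export
self_similarity <- function(x) {
  v <- unclass(x)
  if (!is.matrix(v) || ncol(v) < 2) abort("need a feature matrix with >= 2 frames")
  G <- crossprod(v)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  sigma <- mean(apply(D2, 1, median))
  if (sigma <= 0) {
    abort(sprintf("all %s feature frames are identical; similarity bandwidth is 0",
                  attr(x, "kind") %||% "input"))
  }
  S <- exp(-D2 / sigma)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(S, class = "hierseg_ssm", bandwidth = sigma,
            kind = attr(x, "kind"), frame_rate = attr(x, "frame_rate"))
}

#' @export
print.hierseg_ssm <- function(x, ...) {
  cat(sprintf("<hierseg_ssm: %s> %d x %d, bandwidth %.4g\n",
              attr(x, "kind") %||% "?", nrow(x), ncol(x), attr(x, "bandwidth")))
  invisible(x)
}

#' Center and Frobenius-normalize a square matrix
#'
#' Subtracts the mean entry and scales to unit Frobenius norm, so that the
#' Frobenius inner product of two normalized matrices is a correlation in
#' `[-1, 1]`. The operation is invariant to affine transforms `a * D + b`
#' with `a > 0`, and idempotent.
#'
#' @param d A square numeric matrix; constant matrices are an error.
#' @return The normalized matrix (plain matrix, attributes dropped).
#' @export
normalize_matrix <- function(d) {
  v <- unclass(d)
  if (!is.matrix(v) || nrow(v) != ncol(v)) abort("`d` must be a square matrix")
  v <- v - mean(v)
  fn <- sqrt(sum(v^2))
  if (fn == 0) abort("cannot normalize a constant matrix")
  v / fn
}

#' Correlation of a meet matrix with feature self-similarity matrices
#'
#' After centering and Frobenius-normalizing both sides, the Frobenius inner
#' product `<M^, G^_i>` is the cross-correlation between the vectorized
#' annotation meet matrix and the `i`-th feature similarity matrix: the
#' degree to which the annotation's structure is visible in that acoustic
#' descriptor. Collected over the four features this is the annotation's
#' z-vector.
#'
#' @param m A meet matrix ([meet_matrix()]) on the same frame grid as the
#'   similarity matrices (conventionally 4 Hz).
#' @param ssms Named list of [self_similarity()] matrices, conventionally
#'   `(tempo, rhythm, chroma, mfcc)`.
#' @return A tibble with columns `feature` and `z` (each `z` in `[-1, 1]`).
#' @export
correlation_vector <- function(m, ssms) {
  if (is.null(names(ssms))) {
    names(ssms) <- vapply(ssms, function(s) attr(s, "kind") %||% "", "")
  }
  mh <- normalize_matrix(m)
  z <- vapply(ssms, function(g) {
    if (!identical(dim(unclass(g)), dim(mh))) {
      abort("meet matrix and similarity matrices must share dimensions")
    }
    sum(mh * normalize_matrix(g))
  }, numeric(1))
  tibble(feature = names(ssms), z = unname(z))
}

#' Whitened acoustic distance between two annotations
#'
#' Two annotations of one recording are compared through the acoustic lens:
#' each is reduced to its z-vector of feature correlations
#' ([correlation_vector()]), and the squared difference is measured in the
#' metric of the inverse Gram matrix `W[i, j] = <G^_i, G^_j>` of the
#' normalized similarity matrices. The whitening discounts directions in
#' which the features are mutually correlated (tempo and rhythm especially),
#' so that `delta` reflects genuinely distinct acoustic commitments. A large
#' `delta` means the two annotations correlate with different subsets of
#' features; `delta` is symmetric in its arguments, zero for identical
#' annotations, and depends on the annotations only through their meet
#' matrices.
#'
#' @param m_ref,m_est Meet matrices of the two annotations on the similarity
#'   matrices' frame grid.
#' @param ssms Named list of four [self_similarity()] matrices.
#' @param rcond_cutoff When the reciprocal condition number of `W` falls
#'   below this, the Moore-Penrose pseudo-inverse is used instead of
#'   `solve()` (with a message): near-duplicate features make `W` nearly
#'   singular.
#' @return An object of class `hierseg_delta`: a list with elements `delta`
#'   (the distance), `z` (tibble of both annotations' feature correlations)
#'   and `w` (the 4 x 4 Gram matrix). Supports [tidy()], [glance()].
#' @export
annotation_distance <- function(m_ref, m_est, ssms, rcond_cutoff = 1e-8) {
  z_ref <- correlation_vector(m_ref, ssms)
  z_est <- correlation_vector(m_est, ssms)
  gh <- lapply(ssms, normalize_matrix)
  k <- length(gh)
  W <- matrix(1, k, k, dimnames = list(z_ref$feature, z_ref$feature))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      W[i, j] <- W[j, i] <- sum(gh[[i]] * gh[[j]])
    }
  }
  rc <- rcond(W)
  if (rc < rcond_cutoff) {
    inform(sprintf(
      "similarity Gram matrix is near-singular (rcond = %.2e); using pseudo-inverse", rc))
    Winv <- MASS::ginv(W)
  } else {
    Winv <- solve(W)
  }
  dz <- z_ref$z - z_est$z
  delta <- drop(t(dz) %*% Winv %*% dz)
  structure(
    list(
      delta = max(delta, 0),
      z = dplyr::bind_rows(ref = z_ref, est = z_est, .id = "annotation"),
      w = W
    ),
    class = "hierseg_delta"
  )
}

#' @export
print.hierseg_delta <- function(x, ...) {
  cat(sprintf("<hierseg_delta> delta = %.4f\n", x$delta))
  zw <- tidyr::pivot_wider(x$z, names_from = "annotation", values_from = "z")
  print(as.data.frame(zw), row.names = FALSE)
  invisible(x)
}
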