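# Shared fixtures built in code. Everything is deterministic under the seeds
# fixed here.

# A frame spectrum with prescribed dB amplitudes at chosen bin frequencies
# (all other bins at the floor). fs = 16 kHz, nfft = 128 -> 125-Hz bins.
make_spectrum <- function(db_at = c(), floor_db = -120, fs = 16000, nfft = 128) {
  freqs <- (0:(nfft / 2)) * fs / nfft
  mags <- rep(10^(floor_db / 20), length(freqs))
  for (f in names(db_at)) {
    mags[which.min(abs(freqs - as.numeric(f)))] <- 10^(db_at[[f]] / 20)
  }
  structure(list(magnitudes = mags, bin_freqs_hz = freqs, fs = fs, nfft = nfft),
            class = "frame_spectrum")
}

# Brute-force weighted spectral moments: an independent loop-based summation.
brute_moments <- function(mags, freqs, band = c(1000, 8000)) {
  keep <- freqs >= band[1] & freqs <= band[2]
  f <- freqs[keep]
  p <- mags[keep]^2
  p <- p / sum(p)
  m1 <- 0
  for (k in seq_along(f)) m1 <- m1 + f[k] * p[k]
  m2 <- m3 <- m4 <- 0
  for (k in seq_along(f)) {
    m2 <- m2 + (f[k] - m1)^2 * p[k]
    m3 <- m3 + (f[k] - m1)^3 * p[k]
    m4 <- m4 + (f[k] - m1)^4 * p[k]
  }
  c(M1 = m1, M2 = m2, M3 = m3 / m2^1.5, M4 = m4 / m2^2 - 3)
}

# Brute-force Kruskal-Wallis H via explicit average ranks (tiny samples).
brute_kw_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- vapply(x, function(v) {
    sum(x < v) + (sum(x == v) + 1) / 2
  }, numeric(1))
  g <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (k in seq_along(groups)) {
    rk <- r[g == k]
    H <- H + length(rk) * (mean(rk) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Small three-class Gaussian blobs, linearly separable when sep is large.
make_blobs <- function(n_per = 20, sep = 8, d = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), 3, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per * d), n_per, d) + matrix(centers[k, 1:d], n_per, d,
                                                byrow = TRUE)
  }))
  list(X = X, y = factor(rep(FRIC_GROUPS, each = n_per), levels = FRIC_GROUPS))
}

# Small grid + corpus used by pipeline-level tests (scaled down for speed;
# the full defaults are exercised in test-acceptance.R).
small_grid <- function(seed = 1) {
  grid_search_spec(C_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1),
                   folds = 3, seed = seed)
}
small_corpus_spec <- function(seed = 1, n = 12) {
  corpus_spec(n_tokens_per_group = n, n_talkers = 5, n_train_talkers = 3,
              seed = seed)
}
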