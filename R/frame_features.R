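# Frame cutting and the nine frame-level feature sets: spectral moments,
# peak, slope, MFCC(3)/MFCC(13), Gammatone(14)/Gammatone(24), FFT magnitudes.

FEATURE_SETS <- c("m14", "m14ps", "mfcc3", "mfcc13", "gt14", "gt24", "fftmag")

#' Cut a token into 8-ms frames
#'
#' Training uses one randomly chosen frame per token (`mode = "random_one"`);
#' testing uses every consecutive non-overlapping frame (`mode = "all"`,
#' partial tail dropped). Tokens shorter than one frame are zero-padded to
#' exactly one frame.
#'
#' @param token a [phone_token()] (or [utterance()]).
#' @param frame_ms frame length in milliseconds (default 8).
#' @param mode `"all"` or `"random_one"`.
#' @param seed seed for the random frame draw (`random_one` only).
#' @return numeric matrix, one frame per row.
#' @export
frame_token <- function(token, frame_ms = 8, mode = c("all", "random_one"),
                        seed = 1) {
  mode <- match.arg(mode)
  x <- token$samples
  if (length(x) == 0) stop("empty token")
  L <- round(frame_ms * token$fs / 1000)
  if (L < 16) stop("frame too short: needs at least 16 samples")
  n <- length(x)
  if (n < L) {
    return(matrix(c(x, numeric(L - n)), nrow = 1))
  }
  if (mode == "random_one") {
    start <- with_seed(seed, sample.int(n - L + 1, 1))
    return(matrix(x[start:(start + L - 1)], nrow = 1))
  }
  k <- n %/% L
  matrix(x[1:(k * L)], nrow = k, byrow = TRUE)
}

#' Hamming-windowed magnitude spectrum of a frame
#'
#' @param frame numeric vector, length at most `nfft`.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length, a power of two (default 128; 125-Hz bins at
#'   16 kHz).
#' @return object of class `frame_spectrum`: list with `magnitudes` (bins 0
#'   to Nyquist), `bin_freqs_hz`, `fs`, `nfft`.
#' @export
magnitude_spectrum <- function(frame, fs, nfft = 128) {
  if (nfft < 2 || bitwAnd(nfft, nfft - 1L) != 0) {
    stop("nfft must be a power of two")
  }
  if (length(frame) > nfft) stop("frame longer than nfft")
  w <- frame * hamming_window(length(frame))
  x <- c(w, numeric(nfft - length(w)))
  X <- fft(x)[1:(nfft / 2 + 1)]
  structure(list(magnitudes = Mod(X),
                 bin_freqs_hz = (0:(nfft / 2)) * fs / nfft,
                 fs = fs, nfft = nfft),
            class = "frame_spectrum")
}

in_band <- function(s, band) {
  which(s$bin_freqs_hz >= band[1] & s$bin_freqs_hz <= band[2])
}

#' Four spectral moments of a frame spectrum
#'
#' The normalized in-band power `|X_k|^2 / sum |X|^2` is treated as a
#' probability mass over bin frequencies. M1 is the spectral mean (Hz), M2
#' the variance (Hz^2), M3 the standardized skewness and M4 the *excess*
#' kurtosis (both unitless). With `mass = "db"` the dB amplitudes (shifted to
#' be nonnegative) are used as mass instead, for sensitivity checks.
#'
#' @param s a [magnitude_spectrum()] result.
#' @param band analysis band in Hz (default `c(1000, 8000)`).
#' @param mass `"power"` (default) or `"db"`.
#' @return named vector `c(M1, M2, M3, M4)`. If all in-band mass sits in one
#'   bin (M2 = 0), M3 and M4 are 0 by convention and attribute `degenerate`
#'   is `TRUE`.
#' @export
spectral_moments <- function(s, band = c(1000, 8000), mass = c("power", "db")) {
  mass <- match.arg(mass)
  idx <- in_band(s, band)
  if (length(idx) < 2) stop("need at least 2 bins in band")
  f <- s$bin_freqs_hz[idx]
  p <- if (mass == "power") {
    s$magnitudes[idx]^2
  } else {
    db <- 20 * log10(pmax(s$magnitudes[idx], 1e-10))
    db - min(db)
  }
  tot <- sum(p)
  if (tot == 0) stop("all in-band power is zero")
  p <- p / tot
  m1 <- sum(f * p)
  m2 <- sum((f - m1)^2 * p)
  if (m2 == 0) {
    out <- c(M1 = m1, M2 = 0, M3 = 0, M4 = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  m3 <- sum((f - m1)^3 * p) / m2^1.5
  m4 <- sum((f - m1)^4 * p) / m2^2 - 3
  c(M1 = m1, M2 = m2, M3 = m3, M4 = m4)
}

#' Dominant spectral peak location
#'
#' Frequency of the maximum in-band magnitude; ties break toward the lowest
#' frequency.
#'
#' @inheritParams spectral_moments
#' @return peak frequency in Hz.
#' @export
spectral_peak <- function(s, band = c(1000, 8000)) {
  idx <- in_band(s, band)
  if (length(idx) == 0) stop("empty analysis band")
  s$bin_freqs_hz[idx[which.max(s$magnitudes[idx])]]
}

#' Spectral slope
#'
#' Difference between the highest and lowest in-band amplitude (in dB)
#' divided by the corresponding frequency difference; negative when the peak
#' lies below the trough in frequency. A flat spectrum returns 0.
#'
#' @inheritParams spectral_moments
#' @param floor_db dB floor applied before taking logs (default -120).
#' @return slope in dB per Hz.
#' @export
spectral_slope <- function(s, band = c(1000, 8000), floor_db = -120) {
  idx <- in_band(s, band)
  if (length(idx) == 0) stop("empty analysis band")
  db <- 20 * log10(pmax(s$magnitudes[idx], 10^(floor_db / 20)))
  i_max <- which.max(db)
  i_min <- which.min(db)
  f <- s$bin_freqs_hz[idx]
  if (f[i_max] == f[i_min]) return(0)
  (db[i_max] - db[i_min]) / (f[i_max] - f[i_min])
}

# --- mel cepstra ------------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank matrix [n_filters x n_bins] on the FFT bin grid.
mel_filterbank <- function(n_filters, fs, nfft, f_lo = 0, f_hi = 8000) {
  f_hi <- min(f_hi, fs / 2)
  edges <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                         length.out = n_filters + 2))
  bins <- (0:(nfft / 2)) * fs / nfft
  H <- matrix(0, n_filters, length(bins))
  for (k in seq_len(n_filters)) {
    lo <- edges[k]; mid <- edges[k + 1]; hi <- edges[k + 2]
    up <- bins >= lo & bins <= mid
    dn <- bins > mid & bins <= hi
    H[k, up] <- (bins[up] - lo) / (mid - lo)
    H[k, dn] <- (hi - bins[dn]) / (hi - mid)
  }
  H
}

# Orthonormal DCT-II matrix rows 0..(n_out-1) applied to length-n inputs.
dct2_matrix <- function(n_out, n) {
  M <- outer(0:(n_out - 1), 0:(n - 1),
             function(k, j) cos(pi * k * (2 * j + 1) / (2 * n)))
  M <- M * sqrt(2 / n)
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Mel-frequency cepstral coefficients of a single frame
#'
#' Hamming-windowed power spectrum, 20 triangular mel filters spanning
#' 0-8 kHz, log filterbank energies, orthonormal DCT-II. The energy-bearing
#' 0th cepstrum is excluded: `MFCC(13)` is coefficients 1..13 and `MFCC(3)`
#' is exactly its first three entries.
#'
#' @param frame numeric vector.
#' @param fs sampling rate in Hz.
#' @param n_coeffs 3 or 13.
#' @param nfft FFT length (default 128).
#' @param n_filters number of mel filters (default 20).
#' @param floor log floor added to filterbank energies (default 1e-10).
#' @return a `feature_vector`.
#' @export
mfcc_features <- function(frame, fs, n_coeffs = 13, nfft = 128,
                          n_filters = 20, floor = 1e-10) {
  stopifnot(n_coeffs %in% c(3, 13))
  if (length(frame) < 2) stop("frame too short for MFCC analysis")
  s <- magnitude_spectrum(frame, fs, nfft)
  e <- as.numeric(mel_filterbank(n_filters, fs, nfft) %*% (s$magnitudes^2))
  logs <- log(e + floor)
  cep <- as.numeric(dct2_matrix(14, n_filters) %*% logs)[-1]  # drop 0th
  v <- cep[seq_len(n_coeffs)]
  feature_vector(if (n_coeffs == 3) "mfcc3" else "mfcc13", v,
                 paste0("mfcc", seq_len(n_coeffs)))
}

# --- gammatone filterbank ---------------------------------------------------

erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced gammatone filterbank specification
#'
#' Center frequencies equally spaced on the ERB-rate scale. With the default
#' 24 filters on 100-8000 Hz, exactly 14 centers lie above 1 kHz; these form
#' the high-frequency subset used by the Gammatone(14) feature.
#'
#' @param n_filters number of filters (default 24).
#' @param f_lo,f_hi band edges in Hz (defaults 100 and 8000).
#' @param fs sampling rate in Hz.
#' @return object of class `gammatone_bank`: `center_freqs_hz`, `hi_subset`
#'   (indices with center > 1000 Hz), `order` (4), `fs`.
#' @export
gammatone_bank <- function(n_filters = 24, f_lo = 100, f_hi = 8000, fs = 16000) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi <= fs / 2)
  fc <- erb_rate_inv(seq(erb_rate(f_lo), erb_rate(f_hi),
                         length.out = n_filters))
  structure(list(center_freqs_hz = fc, hi_subset = which(fc > 1000),
                 order = 4L, fs = fs),
            class = "gammatone_bank")
}

#' Gammatone filterbank features of a single frame
#'
#' Per filter: the log of (RMS of the 4th-order gammatone-filtered frame +
#' floor). `subset = "gt14"` returns the Gammatone(24) values restricted to
#' the centers above 1 kHz, bit-exactly.
#'
#' @param frame numeric vector.
#' @param bank a [gammatone_bank()]; its `fs` must match `fs`.
#' @param fs sampling rate of the frame in Hz.
#' @param subset `"gt24"` or `"gt14"`.
#' @param floor additive floor before the log (default 1e-10).
#' @return a `feature_vector`.
#' @export
gammatone_features <- function(frame, bank = gammatone_bank(fs = fs), fs = 16000,
                               subset = c("gt24", "gt14"), floor = 1e-10) {
  subset <- match.arg(subset)
  stopifnot(inherits(bank, "gammatone_bank"))
  if (bank$fs != fs) stop("gammatone bank fs does not match the frame fs")
  vals <- log(cpp_gammatone_rms(frame, bank$center_freqs_hz, fs) + floor)
  idx <- if (subset == "gt14") bank$hi_subset else seq_along(vals)
  feature_vector(subset, vals[idx],
                 sprintf("gt_%.0fHz", bank$center_freqs_hz[idx]))
}

#' Raw FFT magnitude features
#'
#' dB magnitudes (with floor) of every FFT bin with frequency between 100 Hz
#' and 8 kHz — 64 bins at fs = 16 kHz with a 128-point FFT (DC excluded).
#'
#' @param s a [magnitude_spectrum()] result.
#' @param floor_db dB floor (default -120).
#' @return a `feature_vector`.
#' @export
fft_features <- function(s, floor_db = -120) {
  idx <- in_band(s, c(100, 8000))
  db <- 20 * log10(pmax(s$magnitudes[idx], 10^(floor_db / 20)))
  feature_vector("fftmag", db, sprintf("fft_%.0fHz", s$bin_freqs_hz[idx]))
}

#' Token-level dominant peak location
#'
#' The median over all non-overlapping 8-ms frames of the per-frame
#' [spectral_peak()]. Per-frame argmax locations fluctuate by several bins
#' for noise-excited spectra; the across-frame median is the robust
#' token-level calibration measurement.
#'
#' @param token a [phone_token()].
#' @param frame_ms frame length (default 8).
#' @param band analysis band (default `c(1000, 8000)` Hz).
#' @param nfft FFT length (default 128).
#' @return peak frequency in Hz.
#' @export
token_spectral_peak <- function(token, frame_ms = 8, band = c(1000, 8000),
                                nfft = 128) {
  fr <- frame_token(token, frame_ms, "all")
  median(apply(fr, 1, function(x) {
    spectral_peak(magnitude_spectrum(x, token$fs, nfft), band)
  }))
}

#' Construct a named feature vector
#'
#' @param feature_set one of `"m14"`, `"m14ps"`, `"mfcc3"`, `"mfcc13"`,
#'   `"gt14"`, `"gt24"`, `"fftmag"`.
#' @param values numeric values.
#' @param names feature names.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(feature_set, values, names) {
  feature_set <- match.arg(feature_set, FEATURE_SETS)
  stopifnot(length(values) == length(names))
  structure(list(feature_set = feature_set,
                 values = as.numeric(values), names = names),
            class = "feature_vector")
}

#' Expected dimensionality of each feature set
#'
#' @return named integer vector over the seven feature sets (at fs = 16 kHz,
#'   nfft = 128 for `fftmag`).
#' @export
feature_dims <- function() {
  c(m14 = 4L, m14ps = 6L, mfcc3 = 3L, mfcc13 = 13L,
    gt14 = 14L, gt24 = 24L, fftmag = 64L)
}

#' Compute one feature set for a single frame
#'
#' Dispatcher used by the training and classification pipeline.
#'
#' @param frame numeric frame.
#' @param fs sampling rate Hz.
#' @param feature_set one of the seven set names (see [feature_dims()]).
#' @param bank optional [gammatone_bank()] (built on demand otherwise).
#' @param nfft FFT length for spectral sets (default 128).
#' @return numeric vector of feature values.
#' @export
compute_frame_features <- function(frame, fs, feature_set, bank = NULL,
                                   nfft = 128) {
  feature_set <- match.arg(feature_set, FEATURE_SETS)
  if (feature_set %in% c("gt14", "gt24")) {
    if (is.null(bank)) bank <- gammatone_bank(fs = fs)
    return(gammatone_features(frame, bank, fs, subset = feature_set)$values)
  }
  if (feature_set %in% c("mfcc3", "mfcc13")) {
    return(mfcc_features(frame, fs, if (feature_set == "mfcc3") 3 else 13,
                         nfft = nfft)$values)
  }
  s <- magnitude_spectrum(frame, fs, nfft)
  if (feature_set == "fftmag") return(fft_features(s)$values)
  m <- spectral_moments(s)
  if (feature_set == "m14") return(unname(m))
  c(unname(m), spectral_peak(s), spectral_slope(s))
}
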