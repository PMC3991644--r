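# Small DSP primitives used across the package. No signal-processing package
# is assumed: the first-order Butterworth, Welch PSD and Hilbert envelope are
# implemented here directly.

#' Root-mean-square of a signal
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Hamming window
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hamming_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Evaluate code with a private RNG stream; the caller's .Random.seed is
# restored afterwards so library functions never perturb user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a base seed and a stream index.
# Keeps everything well inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629L)
}

#' First-order Butterworth lowpass coefficients
#'
#' Bilinear-transform design of a one-pole Butterworth lowpass. The -3 dB
#' point of the (single-pass) magnitude response is at `cutoff_hz`.
#'
#' @param cutoff_hz cutoff frequency in Hz; must lie below Nyquist.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` (length 2) and denominator `a` (length 2,
#'   `a[1] = 1`).
#' @export
butter1_lowpass <- function(cutoff_hz, fs) {
  stopifnot(cutoff_hz > 0, fs > 0)
  if (cutoff_hz >= fs / 2) {
    stop("cutoff frequency must be below the Nyquist frequency")
  }
  wc <- tan(pi * cutoff_hz / fs)    # prewarped analogue cutoff
  k <- wc / (1 + wc)
  list(b = c(k, k), a = c(1, (wc - 1) / (wc + 1)))
}

# Direct-form IIR filtering for short coefficient vectors (zero initial state).
iir_filter <- function(b, a, x) {
  nb <- length(b); na <- length(a)
  v <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                                sides = 1))
  v <- v[nb:length(v)]
  if (na > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Zero-phase (forward-backward) application of a filter, with reflected
# padding to suppress edge transients.
filtfilt1 <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1, 3 * max(length(a), length(b)) * 10)
  pre <- 2 * x[1] - x[seq(np + 1, 2, by = -1)]
  post <- 2 * x[n] - x[seq(n - 1, n - np, by = -1)]
  xp <- c(pre, x, post)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann window and 50% overlap.
#'
#' @param x signal.
#' @param fs sampling rate in Hz.
#' @param nfft segment length (power of two recommended).
#' @return data.frame with `freq_hz` and `psd` (linear power per Hz).
#' @export
welch_psd <- function(x, fs, nfft = 1024) {
  stopifnot(length(x) >= nfft)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))  # Hann
  step <- nfft %/% 2
  starts <- seq(1, length(x) - nfft + 1, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    X <- fft(seg)[1:(nfft %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  u <- sum(w^2) * fs
  psd <- acc / (length(starts) * u)
  # one-sided: double everything but DC and Nyquist
  psd[2:(nfft %/% 2)] <- 2 * psd[2:(nfft %/% 2)]
  data.frame(freq_hz = (0:(nfft %/% 2)) * fs / nfft, psd = psd)
}

#' Hilbert envelope
#'
#' Magnitude of the analytic signal, computed with the FFT method.
#'
#' @param x real signal.
#' @return envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
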