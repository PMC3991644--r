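# Masker synthesis (speech-shaped noise and multi-talker babble) and
# SNR-exact mixing with randomized masker segments.

#' Masker specification
#'
#' @param kind `"ssn"` (speech-shaped noise) or `"babble"`.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz SSN only: first-order Butterworth lowpass cutoff
#'   (default 800 Hz, approximating the long-term average speech spectrum).
#' @param n_talkers babble only: number of summed talker streams (default 12).
#' @param seed integer seed controlling the realization.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("ssn", "babble"), fs = 16000, cutoff_hz = 800,
                       n_talkers = 12, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(fs > 0, cutoff_hz > 0, n_talkers >= 2)
  structure(list(kind = kind, fs = fs, cutoff_hz = cutoff_hz,
                 n_talkers = as.integer(n_talkers), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate speech-shaped noise
#'
#' White Gaussian noise lowpass-filtered by a first-order Butterworth filter
#' (default cutoff 800 Hz), then RMS-equalized. The filter is applied as the
#' exact analog first-order magnitude response `|H(f)| = 1/sqrt(1 +
#' (f/fc)^2)` in the frequency domain (zero-phase), so the noise PSD is
#' -3 dB at the cutoff, -20 dB at 10 fc and rolls off at -6 dB/octave.
#' Discrete-time IIR designs (bilinear or matched-z) distort this response
#' near Nyquist; frequency-domain application keeps the printed contract
#' exact across the whole band.
#'
#' @param duration_s duration in seconds.
#' @param spec a [noise_spec()] with `kind = "ssn"`.
#' @param target_rms output RMS level (default 0.05).
#' @return an [utterance()], reproducible from `spec$seed`.
#' @export
generate_ssn <- function(duration_s, spec = noise_spec("ssn"),
                         target_rms = 0.05) {
  stopifnot(inherits(spec, "noise_spec"), spec$kind == "ssn", duration_s > 0)
  if (spec$cutoff_hz >= spec$fs / 2) {
    stop("SSN cutoff must be below the Nyquist frequency")
  }
  n <- round(duration_s * spec$fs)
  x <- with_seed(spec$seed, rnorm(n))
  f <- seq(0, spec$fs, length.out = n + 1)[1:n]
  f <- pmin(f, spec$fs - f)                      # two-sided frequency axis
  H <- 1 / sqrt(1 + (f / spec$cutoff_hz)^2)
  y <- Re(fft(fft(x) * H, inverse = TRUE)) / n
  rms_equalize(utterance(sprintf("ssn_seed%d", spec$seed), y, spec$fs), target_rms)
}

# One synthetic speech-like stream: SSN carrier amplitude-modulated by a
# low-rate (2-8 Hz) random envelope, emulating syllabic rhythm.
babble_stream <- function(n, fs, cutoff_hz, seed) {
  with_seed(seed, {
    carrier <- rnorm(n)
    co <- butter1_lowpass(cutoff_hz, fs)
    carrier <- iir_filter(co$b, co$a, carrier)
    rate <- runif(1, 2, 8)
    env_co <- butter1_lowpass(rate, fs)
    env <- iir_filter(env_co$b, env_co$a, rnorm(n))
    env <- 1 + env / stats::sd(env)
    env[env < 0] <- 0
    carrier * env
  })
}

#' Synthesize multi-talker babble
#'
#' Sums `n_talkers` independent streams. When a `talker_bank` of recordings
#' is supplied, random contiguous segments of matching length are drawn from
#' the bank; otherwise synthetic speech-like streams (SSN carriers modulated
#' by 2-8 Hz random envelopes) are used. The sum is RMS-equalized.
#'
#' @param duration_s duration in seconds.
#' @param spec a [noise_spec()] with `kind = "babble"`.
#' @param talker_bank optional list of [utterance()] recordings.
#' @param target_rms output RMS (default 0.05).
#' @param n_talkers optional override of `spec$n_talkers` (allows 1 stream
#'   for diagnostics).
#' @return an [utterance()], reproducible from `spec$seed`.
#' @export
synthesize_babble <- function(duration_s, spec = noise_spec("babble"),
                              talker_bank = NULL, target_rms = 0.05,
                              n_talkers = NULL) {
  stopifnot(inherits(spec, "noise_spec"), spec$kind == "babble", duration_s > 0)
  nt <- if (is.null(n_talkers)) spec$n_talkers else as.integer(n_talkers)
  stopifnot(nt >= 1)
  n <- round(duration_s * spec$fs)
  acc <- numeric(n)
  for (k in seq_len(nt)) {
    sk <- child_seed(spec$seed, k)
    if (is.null(talker_bank)) {
      acc <- acc + babble_stream(n, spec$fs, spec$cutoff_hz, sk)
    } else {
      u <- talker_bank[[((k - 1) %% length(talker_bank)) + 1]]
      if (length(u$samples) < n) {
        stop("talker recording shorter than requested babble duration")
      }
      start <- with_seed(sk, sample.int(length(u$samples) - n + 1, 1))
      acc <- acc + u$samples[start:(start + n - 1)]
    }
  }
  rms_equalize(utterance(sprintf("babble_seed%d", spec$seed), acc, spec$fs),
               target_rms)
}

#' Mix speech with a masker at an exact SNR
#'
#' Draws a seeded random contiguous masker segment of matching length,
#' scales it so that `20*log10(rms(speech)/rms(masker segment))` equals
#' `snr_db` exactly, and adds it to the speech.
#'
#' @param speech an [utterance()] (or [phone_token()]).
#' @param masker an [utterance()] at least as long as the speech.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer seed for the segment draw.
#' @return an [utterance()] (or [phone_token()], matching the input class)
#'   with attribute `"masker_segment"` recording the segment start index.
#' @export
mix_at_snr <- function(speech, masker, snr_db, seed = 1) {
  stopifnot(inherits(masker, "utterance"))
  x <- speech$samples
  if (rms(x) == 0) stop("speech has zero RMS")
  n <- length(x)
  m <- masker$samples
  if (length(m) < n) stop("masker shorter than the speech signal")
  start <- with_seed(seed, sample.int(length(m) - n + 1, 1))
  seg <- m[start:(start + n - 1)]
  if (rms(seg) == 0) stop("masker segment has zero RMS")
  seg <- seg * (rms(x) / rms(seg)) / 10^(snr_db / 20)
  out <- speech
  out$samples <- x + seg
  attr(out, "masker_segment") <- start
  attr(out, "snr_db") <- snr_db
  out
}
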