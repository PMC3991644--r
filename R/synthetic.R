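# Synthetic fricative corpus generator. Tokens are stationary spectrally
# shaped noise: a single-resonance envelope (in dB) plus a linear spectral
# tilt, calibrated so the three groups reproduce the canonical peak-location
# medians (non-sibilant ~1750 Hz, alveolar ~4625 Hz, palatal ~3250 Hz) and
# the slope sign pattern (-, +, -). Voiced phones add a low-frequency
# (<1 kHz) component.

GROUP_PHONES <- list(NONSIB = c("f", "th", "v", "dh"),
                     ALV = c("s", "z"),
                     PAL = c("sh", "zh"))
VOICED_PHONES <- c("v", "dh", "z", "zh")

#' Per-group spectral envelope specification
#'
#' @param group one of `FRIC_GROUPS`.
#' @param peak_hz_median median dominant-peak location in Hz (group default:
#'   1750 / 4625 / 3250).
#' @param peak_hz_spread SD of the additive per-token peak jitter in Hz
#'   (default 200).
#' @param bandwidth_hz resonance width below the peak: the envelope is 12 dB
#'   down at one bandwidth (group defaults 2000 / 1200 / 1500 — the
#'   non-sibilants are spectrally diffuse, the alveolars concentrated).
#' @param bandwidth_hi_hz resonance width above the peak; defaults to
#'   `bandwidth_hz` except for the alveolars (1500 vs 1200 below), whose
#'   spectra fall off faster below the peak than above — the low-frequency
#'   side reaches the envelope floor, which keeps the alveolar spectral
#'   slope robustly positive.
#' @param tilt_db_per_khz linear spectral tilt through the peak (group
#'   defaults -2 / +1 / -1, giving the rising sibilant vs falling
#'   non-sibilant/palatal slope signature).
#' @param hf_plateau_db high-frequency plateau level in dB relative to the
#'   peak, applied above the peak (alveolar default -18, the others none):
#'   /s, z/ spectra stay high from the alveolar peak out to Nyquist, which
#'   pins their spectral trough — and hence a positive spectral slope — at
#'   the low-frequency band edge. `NA` disables the plateau.
#' @param level_db_spread SD of the per-token level perturbation in dB
#'   (default 3).
#' @return list of class `class_envelope_spec`.
#' @export
class_envelope_spec <- function(group, peak_hz_median = NULL,
                                peak_hz_spread = 200, bandwidth_hz = NULL,
                                bandwidth_hi_hz = NULL,
                                tilt_db_per_khz = NULL, hf_plateau_db = NULL,
                                level_db_spread = 3) {
  group <- match.arg(group, FRIC_GROUPS)
  defaults <- list(
    NONSIB = list(peak = 1750, bw = 2000, bw_hi = 2000, tilt = -2, plat = NA),
    ALV = list(peak = 4625, bw = 1200, bw_hi = 1500, tilt = 1, plat = -18),
    PAL = list(peak = 3250, bw = 1500, bw_hi = 1500, tilt = -1, plat = NA))[[group]]
  if (is.null(peak_hz_median)) peak_hz_median <- defaults$peak
  if (is.null(bandwidth_hz)) bandwidth_hz <- defaults$bw
  if (is.null(bandwidth_hi_hz)) {
    bandwidth_hi_hz <- if (bandwidth_hz == defaults$bw) defaults$bw_hi else
      bandwidth_hz
  }
  if (is.null(tilt_db_per_khz)) tilt_db_per_khz <- defaults$tilt
  if (is.null(hf_plateau_db)) hf_plateau_db <- defaults$plat
  stopifnot(peak_hz_spread >= 0, level_db_spread >= 0, bandwidth_hz > 0,
            bandwidth_hi_hz > 0)
  structure(list(group = group, peak_hz_median = peak_hz_median,
                 peak_hz_spread = peak_hz_spread, bandwidth_hz = bandwidth_hz,
                 bandwidth_hi_hz = bandwidth_hi_hz,
                 tilt_db_per_khz = tilt_db_per_khz,
                 hf_plateau_db = hf_plateau_db,
                 level_db_spread = level_db_spread),
            class = "class_envelope_spec")
}

#' Default envelope specifications for the three groups
#'
#' @param peak_hz_spread,level_db_spread shared spread overrides (the
#'   "difficulty dial").
#' @return named list of [class_envelope_spec()] objects.
#' @export
default_envelope_specs <- function(peak_hz_spread = 200, level_db_spread = 3) {
  stats::setNames(lapply(FRIC_GROUPS, class_envelope_spec,
                         peak_hz_spread = peak_hz_spread,
                         level_db_spread = level_db_spread), FRIC_GROUPS)
}

#' Corpus specification
#'
#' @param n_tokens_per_group tokens per group in each of the train and test
#'   splits (default 100).
#' @param duration_ms_range uniform token duration range (default 30-150 ms).
#' @param fs sampling rate (default 16000).
#' @param n_talkers total simulated talkers (default 10).
#' @param n_train_talkers talkers assigned to the training split (default 8;
#'   the remaining talkers are test-only, so the splits are talker-disjoint).
#' @param talker_spread SD of the log-normal talker peak-scaling factor
#'   (default 0.06, mimicking vocal-tract length variation).
#' @param seed master corpus seed.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_tokens_per_group = 100,
                        duration_ms_range = c(30, 150), fs = 16000,
                        n_talkers = 10, n_train_talkers = 8,
                        talker_spread = 0.06, seed = 1) {
  stopifnot(n_tokens_per_group >= 1, duration_ms_range[1] >= 8,
            duration_ms_range[2] >= duration_ms_range[1],
            n_train_talkers >= 1, n_talkers > n_train_talkers)
  structure(list(n_tokens_per_group = as.integer(n_tokens_per_group),
                 duration_ms_range = duration_ms_range, fs = fs,
                 n_talkers = as.integer(n_talkers),
                 n_train_talkers = as.integer(n_train_talkers),
                 talker_spread = talker_spread, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate one synthetic fricative token
#'
#' White noise is shaped in the frequency domain by a time-invariant envelope
#' (the spectrum of frication noise is treated as stationary over the token):
#' a parabolic-in-dB resonance at `peak = median * talker_factor + jitter`
#' with the stated bandwidth, plus the linear tilt, floored 80 dB below the
#' envelope maximum. Voiced phones add a low-frequency component below 1 kHz.
#' The token is RMS-equalized to `target_rms` perturbed by the level spread.
#'
#' @param spec a [class_envelope_spec()].
#' @param talker_factor multiplicative talker peak-scaling factor (default 1).
#' @param duration_ms token duration (>= 8 ms).
#' @param fs sampling rate (default 16000).
#' @param seed token seed; the waveform is a deterministic function of all
#'   arguments.
#' @param phone phone label (default: first phone of the group).
#' @param utterance_id provenance id.
#' @param target_rms nominal RMS level (default 0.05).
#' @return a [phone_token()].
#' @export
generate_token <- function(spec, talker_factor = 1, duration_ms = 80,
                           fs = 16000, seed = 1, phone = NULL,
                           utterance_id = "synth", target_rms = 0.05) {
  stopifnot(inherits(spec, "class_envelope_spec"), duration_ms >= 8)
  if (is.null(phone)) phone <- GROUP_PHONES[[spec$group]][1]
  n <- round(duration_ms * fs / 1000)
  with_seed(seed, {
    peak <- spec$peak_hz_median * talker_factor +
      rnorm(1, 0, spec$peak_hz_spread)
    if (peak >= fs / 2) stop("resonance peak lies at or beyond Nyquist")
    if (peak < 200) peak <- 200
    nh <- n %/% 2
    f <- (0:nh) * fs / n
    # Center the (possibly asymmetric) parabola so its argmax after adding
    # the tilt sits exactly at the requested peak: the tilt alone shifts the
    # maximum by tilt * bw^2 / 24000 Hz on the side the tilt points to.
    bw_shift <- if (spec$tilt_db_per_khz >= 0) spec$bandwidth_hi_hz else
      spec$bandwidth_hz
    ctr <- peak - spec$tilt_db_per_khz * bw_shift^2 / 24000
    bw <- ifelse(f < ctr, spec$bandwidth_hz, spec$bandwidth_hi_hz)
    env_db <- -12 * ((f - ctr) / bw)^2 +
      spec$tilt_db_per_khz * (f - ctr) / 1000
    if (!is.na(spec$hf_plateau_db)) {
      env_db[f > ctr] <- pmax(env_db[f > ctr], spec$hf_plateau_db)
    }
    env_db <- pmax(env_db, max(env_db) - 80)
    amp <- 10^(env_db / 20)
    if (phone %in% VOICED_PHONES) {
      lf_db <- -15 - 12 * ((f - 300) / 300)^2
      amp <- amp + 10^(pmax(lf_db, -80) / 20)
    }
    # mirror the half-spectrum onto the full FFT grid
    full <- if (n %% 2 == 0) c(amp, rev(amp[2:nh])) else c(amp, rev(amp[2:(nh + 1)]))
    X <- fft(rnorm(n)) * full
    x <- Re(fft(X, inverse = TRUE)) / n
    level <- target_rms * 10^(rnorm(1, 0, spec$level_db_spread) / 20)
    x <- x * (level / rms(x))
    phone_token(utterance_id, phone, spec$group, x, fs)
  })
}

#' Generate a balanced, talker-disjoint synthetic corpus
#'
#' Produces `n_tokens_per_group` tokens per group for each of the train and
#' test splits. Talkers are simulated as log-normal multiplicative shifts of
#' the resonance peak; train and test draw from disjoint talker sets. The
#' manifest records every per-token seed and parameter, so the corpus is
#' bit-exactly regenerable from the spec alone.
#'
#' @param specs named list of per-group [class_envelope_spec()] (default
#'   [default_envelope_specs()]).
#' @param cs a [corpus_spec()].
#' @return list with `train` and `test` (lists of [phone_token()]),
#'   `talker_factors` and a `manifest` data.frame.
#' @export
generate_corpus <- function(specs = default_envelope_specs(),
                            cs = corpus_spec()) {
  stopifnot(inherits(cs, "corpus_spec"), all(FRIC_GROUPS %in% names(specs)))
  factors <- with_seed(child_seed(cs$seed, 1),
                       exp(rnorm(cs$n_talkers, 0, cs$talker_spread)))
  talker_sets <- list(train = seq_len(cs$n_train_talkers),
                      test = (cs$n_train_talkers + 1):cs$n_talkers)
  out <- list(train = list(), test = list())
  manifest <- list()
  counter <- 0L
  for (split in c("train", "test")) {
    for (group in FRIC_GROUPS) {
      phones <- GROUP_PHONES[[group]]
      for (i in seq_len(cs$n_tokens_per_group)) {
        counter <- counter + 1L
        draw_seed <- child_seed(cs$seed, 1000L + counter)
        draws <- with_seed(draw_seed, list(
          talker = sample(talker_sets[[split]], 1),
          duration = runif(1, cs$duration_ms_range[1], cs$duration_ms_range[2])))
        tok_seed <- child_seed(cs$seed, 100000L + counter)
        phone <- phones[((i - 1) %% length(phones)) + 1]
        tok <- generate_token(specs[[group]],
                              talker_factor = factors[draws$talker],
                              duration_ms = draws$duration, fs = cs$fs,
                              seed = tok_seed, phone = phone,
                              utterance_id = sprintf("synth_%s_t%02d_%04d",
                                                     split, draws$talker, counter))
        out[[split]][[length(out[[split]]) + 1]] <- tok
        manifest[[counter]] <- data.frame(
          split = split, group = group, phone = phone,
          talker = draws$talker, talker_factor = factors[draws$talker],
          duration_ms = draws$duration, seed = tok_seed,
          peak_hz_median = specs[[group]]$peak_hz_median,
          peak_hz_spread = specs[[group]]$peak_hz_spread,
          utterance_id = tok$utterance_id)
      }
    }
  }
  list(train = out$train, test = out$test, talker_factors = factors,
       manifest = do.call(rbind, manifest))
}

#' Write a synthetic corpus to disk
#'
#' One WAV + `.phn` pair per token (the label file spans the whole token)
#' plus a CSV manifest, so generated corpora flow through the corpus reader
#' unchanged.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- 0L
  for (split in c("train", "test")) {
    for (tok in corpus[[split]]) {
      k <- k + 1L
      base <- file.path(dir, sprintf("%s_%05d", split, k))
      write_wav(utterance(tok$utterance_id, tok$samples, tok$fs),
                paste0(base, ".wav"))
      write_phone_labels(data.frame(start = 0, end = length(tok$samples),
                                    label = tok$phone),
                         paste0(base, ".phn"))
    }
  }
  write.csv(corpus$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
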