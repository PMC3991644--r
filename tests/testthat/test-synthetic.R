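# synthetic_fricatives: calibration to the canonical medians, determinism,
# stationarity, corpus bookkeeping and the difficulty dial.

test_that("zero-spread tokens peak at the group medians", {
  targets <- c(NONSIB = 1750, ALV = 4625, PAL = 3250)
  for (group in FRIC_GROUPS) {
    spec <- class_envelope_spec(group, peak_hz_spread = 0, level_db_spread = 0)
    tok <- generate_token(spec, duration_ms = 2000, seed = 5)
    # token-level measurement: median over the 250 8-ms frames
    expect_equal(token_spectral_peak(tok), unname(targets[group]),
                 tolerance = 125 / targets[group])   # within one FFT bin
  }
})

test_that("token generation is deterministic and stationary", {
  spec <- class_envelope_spec("ALV")
  a <- generate_token(spec, duration_ms = 100, seed = 9)
  b <- generate_token(spec, duration_ms = 100, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_false(identical(
    a$samples, generate_token(spec, duration_ms = 100, seed = 10)$samples))

  # stationary by construction: the two halves of a long token agree in
  # median frame peak to within one bin (individual frame argmax locations
  # fluctuate by several bins for noise-excited spectra)
  tok <- generate_token(class_envelope_spec("PAL", peak_hz_spread = 0),
                        duration_ms = 2000, seed = 11)
  half <- length(tok$samples) %/% 2
  first <- phone_token("u", "sh", "PAL", tok$samples[1:half], tok$fs)
  last <- phone_token("u", "sh", "PAL",
                      tok$samples[(half + 1):length(tok$samples)], tok$fs)
  expect_lte(abs(token_spectral_peak(first) - token_spectral_peak(last)), 125)

  expect_error(generate_token(class_envelope_spec("ALV",
                                                  peak_hz_median = 9000)),
               "Nyquist")
})

test_that("corpora are balanced, talker-disjoint and regenerable", {
  cs <- corpus_spec(n_tokens_per_group = 10, seed = 21)
  corp <- generate_corpus(cs = cs)
  expect_length(corp$train, 30)
  expect_length(corp$test, 30)
  groups <- vapply(corp$train, function(t) t$group, "")
  expect_equal(unname(table(groups)[FRIC_GROUPS]), rep(10L, 3),
               ignore_attr = TRUE)

  man <- corp$manifest
  expect_length(intersect(man$talker[man$split == "train"],
                          man$talker[man$split == "test"]), 0)

  # identical spec regenerates byte-identical waveforms
  corp2 <- generate_corpus(cs = cs)
  expect_identical(lapply(corp$train, function(t) t$samples),
                   lapply(corp2$train, function(t) t$samples))

  expect_error(corpus_spec(n_talkers = 4, n_train_talkers = 4), "n_talkers")
})

test_that("per-group peak medians land near the spec medians at n = 100", {
  corp <- generate_corpus(cs = corpus_spec(seed = 31))
  rep <- feature_screening_report(corp$train, seed = 32)
  P <- rep[rep$feature == "P", ]
  expect_lt(abs(P$NONSIB - 1750), 250)
  expect_lt(abs(P$ALV - 4625), 250)
  expect_lt(abs(P$PAL - 3250), 250)
  # strongly separated groups: Kruskal-Wallis p far below 1e-4
  expect_lt(P$p, 1e-4)
})

test_that("written corpora round-trip through the corpus reader", {
  corp <- generate_corpus(cs = small_corpus_spec(seed = 41, n = 2))
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  wavs <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  expect_length(wavs, 12)   # (2 tokens x 3 groups) x 2 splits
  u <- read_wav(wavs[1])
  segs <- read_phone_labels(sub("\\.wav$", ".phn", wavs[1]))
  toks <- extract_fricative_tokens(u, segs)
  expect_length(toks, 1)
  expect_equal(toks[[1]]$group, corp$test[[1]]$group)
  # PCM16 quantization: half a step of absolute error
  expect_lt(max(abs(toks[[1]]$samples - corp$test[[1]]$samples)), 1 / 32767)
})

test_that("raising the spreads makes classification harder", {
  accs <- vapply(c(100, 400, 700), function(spread) {
    cfg <- run_config(seed = 51,
                      specs = default_envelope_specs(peak_hz_spread = spread,
                                                     level_db_spread = 3 + spread / 200),
                      corpus = corpus_spec(n_tokens_per_group = 15,
                                           n_talkers = 5, n_train_talkers = 3),
                      grid = small_grid(), test_snrs_db = c(0),
                      include_quiet = TRUE)
    run <- run_experiment(cfg)
    mean(run$metrics$accuracy)
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})
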