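# frame_features: framing, spectra, moments/peak/slope, MFCC, gammatone, FFT.

fs <- 16000

test_that("frame_token obeys the counting and padding rules", {
  tok <- phone_token("u", "s", "ALV", rnorm(400) / 10, fs)
  expect_equal(nrow(frame_token(tok, 8, "all")), 3)     # floor(400/128)
  tok128 <- phone_token("u", "s", "ALV", rnorm(128) / 10, fs)
  expect_equal(nrow(frame_token(tok128, 8, "all")), 1)
  tok60 <- phone_token("u", "s", "ALV", rnorm(60) / 10, fs)
  fr <- frame_token(tok60, 8, "all")
  expect_equal(dim(fr), c(1, 128))
  expect_equal(fr[1, 61:128], rep(0, 68))               # zero-padded tail
  expect_error(frame_token(phone_token("u", "s", "ALV", numeric(0), fs)),
               "empty")
  # random_one is seeded and returns one full frame
  a <- frame_token(tok, 8, "random_one", seed = 3)
  b <- frame_token(tok, 8, "random_one", seed = 3)
  expect_identical(a, b)
  expect_equal(dim(a), c(1, 128))
})

test_that("magnitude_spectrum locates tones and satisfies Parseval", {
  t <- (0:127) / fs
  s <- magnitude_spectrum(cos(2 * pi * 2000 * t), fs)
  expect_equal(s$bin_freqs_hz[which.max(s$magnitudes)], 2000)
  expect_equal(diff(s$bin_freqs_hz)[1], 125)

  expect_equal(magnitude_spectrum(rep(0, 128), fs)$magnitudes, rep(0, 65))
  expect_error(magnitude_spectrum(rnorm(100), fs, nfft = 100), "power of two")

  # Parseval over the full (two-sided) FFT of the windowed frame
  set.seed(5)
  x <- rnorm(128)
  w <- x * hamming_window(128)
  X <- fft(w)
  expect_equal(sum(Mod(X)^2), 128 * sum(w^2), tolerance = 1e-9)
  # one-sided magnitudes agree with the full FFT on retained bins
  s2 <- magnitude_spectrum(x, fs)
  expect_equal(s2$magnitudes, Mod(X)[1:65])
})

test_that("spectral moments match a brute-force oracle and closed forms", {
  # random spectra vs independent loop-based summation
  set.seed(7)
  for (rep in 1:10) {
    mags <- abs(rnorm(65)) + 0.01
    s <- make_spectrum()
    s$magnitudes <- mags
    expect_equal(spectral_moments(s), brute_moments(mags, s$bin_freqs_hz),
                 tolerance = 1e-9)
  }

  # uniform in-band mass: M1 = 4500 (symmetry), M3 = 0, M4 -> -6/5
  s <- make_spectrum()
  s$magnitudes[s$bin_freqs_hz >= 1000 & s$bin_freqs_hz <= 8000] <- 1
  m <- spectral_moments(s)
  expect_equal(unname(m["M1"]), 4500)
  expect_equal(unname(m["M3"]), 0, tolerance = 1e-12)
  n_bins <- 57   # discrete uniform on 57 bins: excess kurtosis -(6/5)(n^2+1)/(n^2-1)
  expect_equal(unname(m["M4"]), -1.2 * (n_bins^2 + 1) / (n_bins^2 - 1),
               tolerance = 1e-9)

  # degenerate single-bin mass
  s1 <- make_spectrum(c("4000" = 0))
  s1$magnitudes[s1$magnitudes < 0.5] <- 0
  m1 <- spectral_moments(s1)
  expect_equal(unname(m1), c(4000, 0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(m1, "degenerate"))

  s0 <- make_spectrum()
  s0$magnitudes[] <- 0
  expect_error(spectral_moments(s0), "zero")
})

test_that("moments are shift-covariant and scale-invariant", {
  set.seed(8)
  mags <- abs(rnorm(65)) + 0.01
  s <- make_spectrum()
  # keep mass strictly inside the band so a one-bin shift stays in-band
  s$magnitudes[] <- 0
  idx <- 10:55
  s$magnitudes[idx] <- mags[idx]
  shifted <- s
  shifted$magnitudes[] <- 0
  shifted$magnitudes[idx + 1] <- mags[idx]
  m0 <- spectral_moments(s)
  m1 <- spectral_moments(shifted)
  expect_equal(unname(m1["M1"] - m0["M1"]), 125, tolerance = 1e-9)
  expect_equal(m1[c("M2", "M3", "M4")], m0[c("M2", "M3", "M4")],
               tolerance = 1e-9)

  # amplitude scaling leaves M1-M4 and P unchanged (zero bins carry no mass)
  sg <- s
  sg$magnitudes <- s$magnitudes * 7.3
  expect_equal(spectral_moments(sg), m0, tolerance = 1e-9)
  expect_equal(spectral_peak(sg), spectral_peak(s))

  # slope invariance needs every bin above the dB floor (dB differences only
  # cancel when the floor is inactive)
  sp <- make_spectrum()
  sp$magnitudes <- mags
  spg <- sp
  spg$magnitudes <- sp$magnitudes * 7.3
  expect_equal(spectral_slope(spg), spectral_slope(sp), tolerance = 1e-9)
})

test_that("spectral peak uses the lowest-frequency tie rule", {
  expect_equal(spectral_peak(make_spectrum(c("4625" = 0))), 4625)
  expect_equal(spectral_peak(make_spectrum(c("2000" = 10, "5000" = 10))), 2000)
  flat <- make_spectrum()
  flat$magnitudes[] <- 1
  expect_equal(spectral_peak(flat), 1000)   # lowest in-band bin
  expect_error(spectral_peak(flat, band = c(9000, 10000)), "empty")
})

test_that("spectral slope follows the dB-amplitude definition", {
  s <- make_spectrum(c("4625" = 60, "1000" = 20))
  s$magnitudes[s$magnitudes < 10^(19 / 20)] <- 10^(30 / 20)  # fill between
  expect_equal(spectral_slope(s), 40 / 3625, tolerance = 1e-9)

  s2 <- make_spectrum(c("1000" = 30, "6000" = 5))
  s2$magnitudes[s2$magnitudes < 10^(4 / 20)] <- 10^(20 / 20)
  expect_equal(spectral_slope(s2), -25 / 5000, tolerance = 1e-9)

  flat <- make_spectrum()
  flat$magnitudes[] <- 2
  expect_equal(spectral_slope(flat), 0)
})

test_that("MFCC(3) is the exact prefix of MFCC(13) and gain-invariant", {
  set.seed(9)
  x <- rnorm(128) / 5
  m13 <- mfcc_features(x, fs, 13)
  m3 <- mfcc_features(x, fs, 3)
  expect_identical(m3$values, m13$values[1:3])
  expect_length(m13$values, 13)

  # gain shifts only the excluded 0th cepstrum: retained cepstra unchanged
  m13g <- mfcc_features(x * 4.7, fs, 13)
  expect_equal(m13g$values, m13$values, tolerance = 1e-6)

  z <- mfcc_features(rep(0, 128), fs, 13)
  expect_true(all(is.finite(z$values)))
  expect_error(mfcc_features(numeric(1), fs), "short")
})

test_that("the gammatone bank has 14 of 24 centers above 1 kHz, GT14 subset exact", {
  bank <- gammatone_bank()
  expect_equal(length(bank$center_freqs_hz), 24)
  expect_true(all(diff(bank$center_freqs_hz) > 0))
  expect_equal(length(bank$hi_subset), 14)
  expect_equal(bank$hi_subset, 11:24)

  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(128) / 10
    g24 <- gammatone_features(x, bank, fs, "gt24")
    g14 <- gammatone_features(x, bank, fs, "gt14")
    expect_identical(g14$values, g24$values[bank$hi_subset])
  }
})

test_that("gammatone filters are frequency-selective", {
  # narrowband noise at 4 kHz: strongest output at the center nearest 4 kHz
  set.seed(11)
  bank <- gammatone_bank()
  n <- 128
  f <- (0:(n / 2)) * fs / n
  amp <- exp(-((f - 4000) / 150)^2)
  full <- c(amp, rev(amp[2:(n / 2)]))
  x <- Re(fft(fft(rnorm(n)) * full, inverse = TRUE)) / n
  g <- gammatone_features(x, bank, fs, "gt24")
  expect_equal(which.max(g$values),
               which.min(abs(bank$center_freqs_hz - 4000)))
  expect_error(gammatone_features(x, bank, fs = 8000), "fs")
})

test_that("FFT features span 100-8000 Hz and match the spectrum", {
  set.seed(12)
  x <- rnorm(128) / 10
  s <- magnitude_spectrum(x, fs)
  fv <- fft_features(s)
  expect_length(fv$values, 64)                      # bins 1..64, DC excluded
  expect_equal(fv$values, 20 * log10(pmax(s$magnitudes[2:65], 1e-6)))

  # an all-zero frame sits exactly at the dB floor on every retained bin
  fz <- fft_features(magnitude_spectrum(rep(0, 128), fs))
  expect_equal(fz$values, rep(-120, 64))
  # DC-only energy reaches the retained bins only via window leakage
  fd <- fft_features(magnitude_spectrum(rep(0.3, 128), fs))
  expect_true(all(fd$values[10:64] < max(fd$values) - 60))
})

test_that("all seven feature sets have the declared dimensions", {
  set.seed(13)
  x <- rnorm(128) / 10
  dims <- feature_dims()
  for (set in names(dims)) {
    expect_length(compute_frame_features(x, fs, set), dims[[set]])
  }
})
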