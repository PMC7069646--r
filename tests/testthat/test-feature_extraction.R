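# The eight click parameters against closed forms and brute-force oracles.

fs_nom <- 576000

test_that("envelope recovers the modulating amplitude", {
  t <- (0:2047) / fs_nom
  x <- 3.7 * sin(2 * pi * 60000 * t)
  env <- envelope(x)
  expect_equal(stats::median(env[200:1800]), 3.7, tolerance = 0.01)

  g <- oracle_gabor(80, 8, fs_nom, amp = 2)
  env_g <- envelope(g$samples)
  sigma <- 8e-6
  core <- (g$peak_index - 15):(g$peak_index + 15)
  truth <- 2 * exp(-((core - g$peak_index) / fs_nom)^2 / (2 * sigma^2))
  expect_lt(max(abs(env_g[core] - truth) / truth), 0.05)

  expect_true(all(envelope(numeric(64)) == 0))
})

test_that("window extraction follows the centering and edge rules", {
  rec <- audio_recording(seq_len(5000), fs_nom, full_scale_level = 300)
  w <- extract_window(rec, 1000)
  expect_length(w$samples, 32)
  expect_equal(w$samples, as.numeric(984:1015))  # peak-16 .. peak+15
  expect_equal(w$center_index, 17L)
  expect_equal(w$samples[w$center_index], 1000)

  # near the left edge: zero-padded to 32
  w2 <- extract_window(rec, 5)
  expect_length(w2$samples, 32)
  expect_true(all(w2$samples[1:11] == 0))
  expect_equal(w2$samples[w2$center_index], 5)

  const <- extract_window(audio_recording(rep(2, 100), fs_nom,
                                          full_scale_level = 300), 50)
  expect_true(all(const$samples == 2))
})

test_that("-10 dB duration matches the Gaussian closed form and is scale-free", {
  for (sigma_us in c(4, 5, 8)) {
    g <- oracle_gabor(90, sigma_us, fs_nom)
    rec <- audio_recording(g$samples, fs_nom, full_scale_level = 300)
    win <- extract_window(rec, g$peak_index)
    d <- duration_minus10dB(win)
    closed <- 2 * sigma_us * sqrt(log(10))   # ~3.035 sigma
    expect_equal(d, closed, tolerance = 0.05)
  }
  # rectangular envelope of length L: at least L (the envelope never drops
  # below the threshold inside the pulse); the analytic-signal ringing at
  # the edges may add a few samples beyond it
  n_on <- 8
  x <- numeric(32); x[13:(12 + n_on)] <- 1
  win_r <- structure(list(samples = x, sample_rate = fs_nom,
                          center_index = 13L), class = "ClickWindow")
  d_r <- duration_minus10dB(win_r)
  L_us <- n_on / fs_nom * 1e6
  expect_gte(d_r, L_us - 1e-9)
  expect_lte(d_r, L_us + 6 / fs_nom * 1e6)

  # halving the amplitude leaves the duration unchanged
  g <- oracle_gabor(90, 5, fs_nom)
  rec1 <- audio_recording(g$samples, fs_nom, full_scale_level = 300)
  rec2 <- audio_recording(g$samples / 2, fs_nom, full_scale_level = 300)
  expect_equal(duration_minus10dB(extract_window(rec1, g$peak_index)),
               duration_minus10dB(extract_window(rec2, g$peak_index)))
  expect_error(duration_minus10dB(
    structure(list(samples = numeric(32), sample_rate = fs_nom,
                   center_index = 17L), class = "ClickWindow")), "zero")
})

test_that("click spectrum has 1.8 kHz bins and Parseval scaling", {
  g <- oracle_gabor(90, 5, fs_nom)
  win <- extract_window(audio_recording(g$samples, fs_nom,
                                        full_scale_level = 300), g$peak_index)
  spec <- click_spectrum(win)
  expect_equal(diff(spec$frequencies)[1], 1800)
  expect_equal(spec$amplitude, sqrt(spec$power))

  # bin-centred tone at 90 kHz (a multiple of 18 kHz) peaks at 90 kHz
  tone <- sin(2 * pi * 90000 * (0:31) / fs_nom)
  win_t <- structure(list(samples = tone, sample_rate = fs_nom,
                          center_index = 17L), class = "ClickWindow")
  spec_t <- click_spectrum(win_t)
  expect_equal(spec_t$frequencies[which.max(spec_t$power)], 90000)

  # white noise: one-sided power sums to the variance / interp factor
  set.seed(3)
  tot <- replicate(200, {
    wn <- structure(list(samples = rnorm(32), sample_rate = fs_nom,
                         center_index = 17L), class = "ClickWindow")
    s <- click_spectrum(wn)
    sum(s$power) / s$interp_factor
  })
  expect_equal(mean(tot), 1, tolerance = 0.1)

  # interpolated spectrum agrees with a dense direct DFT oracle
  dense <- oracle_windowed_power(win$samples, fs_nom,
                                 spec$frequencies[2:160])
  expect_equal(spec$power[2:160], dense, tolerance = 1e-9)
})

test_that("peak and centroid frequency match definitions and oracles", {
  freqs <- seq(0, 288000, by = 1800)
  delta <- function(f0) {
    p <- numeric(length(freqs)); p[which.min(abs(freqs - f0))] <- 1
    oracle_spectrum(freqs, p)
  }
  expect_equal(peak_frequency(delta(72000)), 72)
  expect_equal(centroid_frequency(delta(63000)), 63)

  # two equal tones at 40 and 80 kHz: centroid 60 kHz, RMS bandwidth 20 kHz
  p2 <- numeric(length(freqs))
  p2[freqs %in% c(39600, 79200)] <- 1  # nearest grid points
  two <- oracle_spectrum(freqs, p2)
  expect_equal(centroid_frequency(two), mean(c(39.6, 79.2)))
  expect_equal(rms_bandwidth(two), (79.2 - 39.6) / 2)

  # symmetric spectrum about 80 kHz -> centroid 80 kHz
  sym <- oracle_spectrum(freqs, exp(-((freqs - 80000) / 20000)^2))
  expect_equal(centroid_frequency(sym), 80, tolerance = 1e-4)

  # ties in peak power resolve to the lowest frequency
  expect_equal(peak_frequency(two), 39.6)

  # Gabor synthesized at 97 kHz: spectral peak within one interpolated bin
  g <- oracle_gabor(97, 5, fs_nom)
  spec <- click_spectrum(extract_window(
    audio_recording(g$samples, fs_nom, full_scale_level = 300),
    g$peak_index))
  expect_lt(abs(peak_frequency(spec) - 97), 1.8)
  expect_lt(abs(centroid_frequency(spec) - 97), 2)
})

test_that("centroid and RMS bandwidth equal brute-force summation to 1e-9", {
  set.seed(12)
  for (i in 1:10) {
    freqs <- seq(0, 288000, by = 1800)
    p <- rexp(length(freqs))
    spec <- oracle_spectrum(freqs, p)
    expect_equal(centroid_frequency(spec), oracle_centroid_khz(spec),
                 tolerance = 1e-9)
    expect_equal(rms_bandwidth(spec), oracle_rms_bw_khz(spec),
                 tolerance = 1e-9)
  }
})

test_that("dB bandwidths follow thresholds, closed forms and nesting", {
  freqs <- seq(0, 288000, by = 180)   # fine grid for the closed form
  sigma_f <- 15000
  gauss <- oracle_spectrum(freqs, exp(-((freqs - 100000)^2) / (2 * sigma_f^2)))
  b3 <- db_bandwidth(gauss, 3)
  b10 <- db_bandwidth(gauss, 10)
  expect_equal(b3$bandwidth_khz, 2 * sqrt(2 * log(10^0.3)) * sigma_f / 1000,
               tolerance = 0.01)   # ~2.355 sigma_f
  expect_equal(b10$bandwidth_khz, 2 * sqrt(2 * log(10)) * sigma_f / 1000,
               tolerance = 0.01)
  expect_lte(b3$bandwidth_khz, b10$bandwidth_khz)
  expect_lte(b10$lower_khz, b3$lower_khz)
  expect_equal(b3$lower_khz, 100 - sqrt(2 * log(10^0.3)) * 15,
               tolerance = 0.05)

  # single occupied interpolated bin: bandwidth at most one bin spacing
  coarse <- seq(0, 288000, by = 1800)
  one <- numeric(length(coarse)); one[60] <- 1
  b_one <- db_bandwidth(oracle_spectrum(coarse, one), 3)
  expect_lte(b_one$bandwidth_khz, 1.8 + 1e-9)

  # flat spectrum never crosses the threshold: full band, flagged
  flat <- oracle_spectrum(coarse, rep(1, length(coarse)))
  b_flat <- db_bandwidth(flat, 3)
  expect_true(b_flat$flagged)
  expect_equal(b_flat$lower_khz, 10.8)  # first bin inside the 10-200 band
})

test_that("flat power over a band has RMS bandwidth (b-a)/sqrt(12)", {
  freqs <- seq(0, 288000, by = 180)
  p <- as.numeric(freqs >= 60000 & freqs <= 120000)
  expect_equal(rms_bandwidth(oracle_spectrum(freqs, p)), 60 / sqrt(12),
               tolerance = 0.01)
})

test_that("the assembled feature record is complete, ordered and scale-free", {
  g <- oracle_gabor(85, 5, fs_nom, amp = 1000)
  rec <- audio_recording(g$samples, fs_nom, full_scale_level = 300)
  cand <- click_candidate(g$peak_index, 1000, fs_nom)
  ft <- extract_features(cand, rec, species = "A", session_id = "s",
                         train_id = "t")
  expect_true(all(click_parameters() %in% names(ft)))
  expect_true(ft$lower10_khz <= ft$lower3_khz)
  expect_true(ft$lower3_khz <= ft$peak_khz)
  expect_true(ft$bw3_khz <= ft$bw10_khz)
  expect_true(all(ft[click_parameters()] > 0))

  rec2 <- audio_recording(g$samples * 12.5, fs_nom, full_scale_level = 300)
  ft2 <- extract_features(cand, rec2, species = "A")
  expect_equal(as.numeric(ft2[click_parameters()]),
               as.numeric(ft[click_parameters()]), tolerance = 1e-12)

  zero <- audio_recording(numeric(2000), fs_nom)
  expect_error(extract_features(click_candidate(1000, 0, fs_nom), zero),
               "zero")
})

test_that("parameters are recovered from rendered clicks at high SNR", {
  # trains spanning the two species' frequency ranges, rendered into noise
  fcs <- c(55, 70, 85, 97, 110)
  trains <- lapply(seq_along(fcs), function(i)
    train_model(20, mean_ici = 0.018, start_time = 0.05 + (i - 1) * 0.4,
                snr_db = 30, center_khz = fcs[i],
                sigma_us = 4 + i %% 3))
  sc <- render_scene(scene_spec(2.1, trains, seed = 77))
  f <- bandpass(sc$recording)
  err_fp <- err_fc <- numeric(0)
  for (i in seq_len(nrow(sc$truth))) {
    idx <- round(sc$truth$time_s[i] * fs_nom) + 1
    loc <- envelope(f$samples[(idx - 40):(idx + 40)])
    peak <- idx - 41 + which.max(loc)
    ft <- extract_features(click_candidate(peak, max(loc), fs_nom), f)
    err_fp <- c(err_fp, abs(ft$peak_khz - sc$truth$center_khz[i]))
    err_fc <- c(err_fc, abs(ft$centroid_khz - sc$truth$center_khz[i]))
  }
  expect_gte(length(err_fp), 100)
  expect_lt(stats::median(err_fp), 1.8)  # one interpolated bin
  expect_lt(stats::median(err_fc), 2)
})
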