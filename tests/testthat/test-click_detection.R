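# Spectral energy detector: segment spectra, noise floor, the per-bin SNR
# criterion and false-positive screening.

test_that("segment spectra have the stated grid and Parseval scaling", {
  fs <- 576000
  # zero signal -> all-zero spectra
  z <- segment_spectra(audio_recording(numeric(fs %/% 10), fs))
  expect_true(all(z$power == 0))
  expect_equal(diff(z$frequencies)[1], 1000)  # 1 kHz bins at 576 kHz

  # bin-aligned 72 kHz tone peaks at the 72 kHz bin in every segment
  t <- (0:(fs %/% 10 - 1)) / fs
  tone <- audio_recording(sin(2 * pi * 72000 * t), fs, full_scale_level = 60)
  sp <- segment_spectra(tone)
  peaks <- sp$frequencies[apply(sp$power, 2, which.max)]
  expect_true(all(peaks == 72000))

  # white noise: mean total one-sided power matches the variance within 10%
  set.seed(1)
  wn <- audio_recording(rnorm(fs %/% 10, sd = 0.3), fs, full_scale_level = 60)
  spn <- segment_spectra(wn)
  expect_equal(mean(colSums(spn$power)), 0.09, tolerance = 0.1)
})

test_that("too-short recordings give an empty result with a warning", {
  expect_warning(sp <- segment_spectra(audio_recording(numeric(100), 576000)),
                 "shorter")
  expect_equal(ncol(sp$power), 0)
})

test_that("noise spectrum is a robust per-bin floor", {
  fs <- 576000
  # identical segments -> noise spectrum equals the common spectrum
  seg <- sin(2 * pi * 50000 * (0:2879) / fs)
  rec <- audio_recording(rep(seg, 8), fs, full_scale_level = 60)
  sp <- segment_spectra(rec)
  ns <- estimate_noise_spectrum(sp)
  expect_equal(ns$power, sp$power[, 1], tolerance = 1e-6)

  # all-zero input -> all-zero noise floor
  spz <- segment_spectra(audio_recording(numeric(2880 * 6), fs))
  expect_true(all(estimate_noise_spectrum(spz)$power == 0))
  expect_error(estimate_noise_spectrum(
    segment_spectra(audio_recording(numeric(2880 * 3), fs))), "5 segments")

  # stationary noise with sparse clicks: floor within 1 dB of the
  # click-free segments' mean, in the detection band
  sc <- render_scene(scene_spec(2, list(train_model(4, mean_ici = 0.45,
                                                    start_time = 0.2,
                                                    snr_db = 35)),
                                seed = 5))
  f <- bandpass(sc$recording)
  spc <- segment_spectra(f)
  nsc <- estimate_noise_spectrum(spc)
  click_segs <- unique(floor(sc$truth$time_s / 0.005) + 1)
  clean_mean <- rowMeans(spc$power[, -click_segs])
  band <- spc$frequencies >= 20000 & spc$frequencies <= 90000
  err_db <- abs(10 * log10(nsc$power[band] / clean_mean[band]))
  expect_lt(stats::median(err_db), 1)
})

test_that("detector finds injected clicks and ignores pure noise", {
  # pure noise: no candidates at the 15 dB / 13% criterion
  noise_only <- render_scene(scene_spec(1.5, seed = 21))
  f0 <- bandpass(noise_only$recording)
  sp0 <- segment_spectra(f0)
  cands0 <- detect_candidates(f0, noise = estimate_noise_spectrum(sp0),
                              spectra = sp0)
  expect_length(cands0, 0)

  # one strong Gabor click: exactly one candidate within 0.5 ms of truth
  one <- render_scene(scene_spec(
    1, list(train_model(1, start_time = 0.4321, snr_db = 30,
                        center_khz = 60)), seed = 8))
  f1 <- bandpass(one$recording)
  sp1 <- segment_spectra(f1)
  cands1 <- detect_candidates(f1, noise = estimate_noise_spectrum(sp1),
                              spectra = sp1)
  expect_length(cands1, 1)
  expect_lt(abs(cands1[[1]]$time_s - one$truth$time_s), 5e-4)

  # click with all energy below the 15 kHz band edge: not detected
  low <- render_scene(scene_spec(
    1, list(train_model(1, start_time = 0.5, snr_db = 30,
                        center_khz = 8, sigma_us = 60)), seed = 9))
  fl <- bandpass(low$recording)
  spl <- segment_spectra(fl)
  candsl <- detect_candidates(fl, noise = estimate_noise_spectrum(spl),
                              spectra = spl)
  expect_lt(oracle_recall(low$truth$time_s,
                          vapply(candsl, `[[`, 1, "time_s")) , 1)
})

test_that("detection probability is monotone in click SNR", {
  recall_at <- function(snr) {
    sc <- render_scene(scene_spec(
      1.2, list(train_model(8, mean_ici = 0.05, start_time = 0.3,
                            snr_db = snr, center_khz = 80)), seed = 31))
    f <- bandpass(sc$recording)
    sp <- segment_spectra(f)
    cands <- detect_candidates(f, noise = estimate_noise_spectrum(sp),
                               spectra = sp)
    oracle_recall(sc$truth$time_s, vapply(cands, `[[`, 1, "time_s"))
  }
  r25 <- recall_at(25); r5 <- recall_at(5)
  expect_gte(r25, 0.95)
  expect_lte(r5, r25)
  expect_lt(r5, 0.5)
})

test_that("false-positive screening drops low-frequency and clipped clicks", {
  fs <- 576000
  pfs <- full_scale_pressure(173)
  rec <- audio_recording(numeric(fs %/% 50), fs)
  mk <- function(fc_khz, frac_fs, at) {
    g <- oracle_gabor(fc_khz, if (fc_khz < 15) 80 else 6, fs,
                      amp = frac_fs * pfs, pad = 0)
    i0 <- at
    rec$samples[i0:(i0 + length(g$samples) - 1)] <<- g$samples
    click_candidate(i0 + g$peak_index - 1, frac_fs * pfs, fs,
                    waveform = g$samples)
  }
  c_low  <- mk(10, 0.5, 1000)    # spectral peak ~10 kHz -> false positive
  c_clip <- mk(60, 0.95, 4000)   # 95% of full scale -> clipped
  c_good <- mk(60, 0.5, 8000)
  kept <- remove_false_positives(list(c_low, c_clip, c_good), rec = rec)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$time_index, c_good$time_index)
  rej <- attr(kept, "rejected")
  flags <- lapply(rej, `[[`, "flags")
  expect_true(any(vapply(flags, function(f) "low_peak_frequency" %in% f, TRUE)))
  expect_true(any(vapply(flags, function(f) "clipped" %in% f, TRUE)))

  # never grows the set; idempotent
  kept2 <- remove_false_positives(kept, rec = rec)
  expect_length(kept2, length(kept))
  expect_equal(candidates_table(kept2), candidates_table(kept))
})

test_that("highest-amplitude selection obeys the tie rule", {
  mk <- function(i, a) click_candidate(i, a, 576000)
  tr <- list(mk(100, 3), mk(200, 9), mk(300, 5))
  expect_equal(select_highest_amplitude(tr)$time_index, 200)
  expect_equal(select_highest_amplitude(list(mk(50, 7)))$time_index, 50)
  tie <- list(mk(400, 7), mk(150, 7))
  expect_equal(select_highest_amplitude(tie)$time_index, 150)  # earlier wins
  expect_error(select_highest_amplitude(list()), "empty")
  # selected amplitude dominates the train
  sel <- select_highest_amplitude(tr)
  expect_true(all(sel$peak_amplitude >=
                    vapply(tr, `[[`, 1, "peak_amplitude")))
})
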