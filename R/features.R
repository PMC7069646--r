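# The eight per-click acoustic parameters:
#   -10 dB duration; peak, centroid, lower -3 dB and lower -10 dB
#   frequencies; -3 dB, -10 dB and RMS bandwidths.
# All spectral parameters come from a 32-point Hanning-windowed power
# spectrum of the samples around the envelope peak, interpolated by a
# factor of 10 (1.8 kHz bins at 576 kHz).

CLICK_PARAMETERS <- c("duration_us", "peak_khz", "centroid_khz",
                      "lower3_khz", "lower10_khz",
                      "bw3_khz", "bw10_khz", "bwrms_khz")

CLICK_PARAMETER_LABELS <- c(
  duration_us  = "-10 dB duration (us)",
  peak_khz     = "Peak frequency (kHz)",
  centroid_khz = "Centroid frequency (kHz)",
  lower3_khz   = "Lower -3 dB frequency (kHz)",
  lower10_khz  = "Lower -10 dB frequency (kHz)",
  bw3_khz      = "-3 dB bandwidth (kHz)",
  bw10_khz     = "-10 dB bandwidth (kHz)",
  bwrms_khz    = "RMS bandwidth (kHz)")

#' Names of the eight click parameters
#'
#' @param labels if TRUE, return the human-readable labels instead of the
#'   column names.
#' @return character vector of length 8.
#' @export
click_parameters <- function(labels = FALSE) {
  if (labels) unname(CLICK_PARAMETER_LABELS) else CLICK_PARAMETERS
}

#' Signal envelope (analytic-signal magnitude)
#'
#' Magnitude of the Hilbert analytic signal, computed in the frequency
#' domain. For a narrowband pulse a(t) cos(2 pi f t) the result
#' approximates |a(t)| away from the record edges.
#'
#' @param x numeric waveform.
#' @return nonnegative envelope, same length as `x`.
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' 32-sample analysis window around a click
#'
#' @param rec an `AudioRecording`.
#' @param time_index 1-based sample index of the click's envelope peak.
#' @param size window length in samples (default 32).
#' @return a `ClickWindow`: `samples` (length `size`, zero-padded at
#'   recording edges), `sample_rate`, `center_index` (position of the peak,
#'   `size/2 + 1`).
#' @export
extract_window <- function(rec, time_index, size = 32) {
  stopifnot(inherits(rec, "AudioRecording"),
            time_index >= 1, time_index <= length(rec$samples))
  half <- size %/% 2
  idx <- (time_index - half):(time_index + half - 1)
  samples <- numeric(size)
  ok <- idx >= 1 & idx <= length(rec$samples)
  samples[ok] <- rec$samples[idx[ok]]
  structure(list(samples = samples, sample_rate = rec$sample_rate,
                 center_index = half + 1L),
            class = "ClickWindow")
}

#' Click window from a raw waveform snippet
#'
#' Centers the analysis window on the envelope peak of the snippet.
#'
#' @param samples numeric waveform containing one click.
#' @param sample_rate sampling rate (Hz).
#' @param size window length in samples (default 32).
#' @return a `ClickWindow`.
#' @export
click_window <- function(samples, sample_rate, size = 32) {
  if (length(samples) < size) {
    pad <- size - length(samples)
    samples <- c(samples, numeric(pad))
  }
  peak <- which.max(envelope(samples))
  rec <- audio_recording(samples, sample_rate, full_scale_level = 300)
  extract_window(rec, peak, size = size)
}

#' -10 dB duration of a click, microseconds
#'
#' The envelope of the window is linearly interpolated by `interp_factor`
#' (default 10) and the duration is the time between the first and last
#' crossings of one tenth-power of the envelope peak
#' (amplitude threshold `peak x 10^(-10/20)`). Invariant to amplitude
#' scaling.
#'
#' @param win a `ClickWindow`.
#' @param drop threshold below the envelope peak, dB (default 10).
#' @param interp_factor waveform interpolation factor (default 10).
#' @return duration in microseconds.
#' @export
duration_minus10dB <- function(win, drop = 10, interp_factor = 10) {
  stopifnot(inherits(win, "ClickWindow"))
  if (all(win$samples == 0)) stop("all-zero click window")
  env <- envelope(win$samples)
  n <- length(env)
  dt <- 1 / win$sample_rate
  t0 <- (seq_len(n) - 1) * dt
  tf <- seq(0, t0[n], by = dt / interp_factor)
  fine <- stats::approx(t0, env, xout = tf)$y
  thr <- max(fine) * 10^(-drop / 20)
  above <- which(fine >= thr)
  i1 <- above[1]; i2 <- above[length(above)]
  cross <- function(a, b) {
    # linear crossing time between fine samples a (below) and b (above thr)
    if (a < 1 || fine[b] == fine[a]) return(tf[b])
    tf[a] + (thr - fine[a]) / (fine[b] - fine[a]) * (tf[b] - tf[a])
  }
  t_start <- if (i1 > 1) cross(i1 - 1, i1) else tf[i1]
  t_end <- if (i2 < length(fine)) {
    if (fine[i2 + 1] == fine[i2]) tf[i2]
    else tf[i2] + (thr - fine[i2]) / (fine[i2 + 1] - fine[i2]) * (tf[i2 + 1] - tf[i2])
  } else tf[i2]
  (t_end - t_start) * 1e6
}

#' Power spectrum of a click window
#'
#' Modified periodogram of the 32-sample window (Hanning window, 32-point
#' FFT — the one-frame degenerate case of a Welch estimate), interpolated
#' by a factor of 10 by zero-padding the windowed waveform before the FFT
#' (band-limited low-pass interpolation of the spectrum). Bin spacing is
#' `sample_rate / (32 * 10)`: 1.8 kHz at 576 kHz.
#'
#' @param win a `ClickWindow`.
#' @param interp_factor spectral interpolation factor (default 10).
#' @return a `ClickSpectrum`: `frequencies` (Hz, one-sided), `power`
#'   (linear one-sided power; its sum divided by `interp_factor`
#'   approximates the windowed signal's mean square up to window gain),
#'   `amplitude` (= sqrt(power)), `sample_rate`, `interp_factor`.
#' @export
click_spectrum <- function(win, interp_factor = 10) {
  stopifnot(inherits(win, "ClickWindow"))
  n <- length(win$samples)
  w <- signal::hanning(n)
  xw <- win$samples * w
  npad <- n * interp_factor
  X <- stats::fft(c(xw, numeric(npad - n)))
  p2 <- Mod(X)^2 / (n * sum(w^2))
  half <- npad %/% 2
  power <- p2[1:(half + 1)]
  power[2:half] <- 2 * power[2:half]
  freqs <- (0:half) * win$sample_rate / npad
  structure(list(frequencies = freqs, power = power,
                 amplitude = sqrt(power),
                 sample_rate = win$sample_rate,
                 interp_factor = interp_factor),
            class = "ClickSpectrum")
}

# Default analysis band: the 10-200 kHz preprocessing filter band, so bins
# the band-pass removed are excluded from spectral sums.
ANALYSIS_BAND_HZ <- c(10000, 200000)

band_index <- function(spec, band) {
  which(spec$frequencies >= band[1] & spec$frequencies <= band[2])
}

#' Peak frequency, kHz
#'
#' Frequency of the maximum-power bin within the analysis band; ties break
#' to the lowest frequency.
#'
#' @param spec a `ClickSpectrum`.
#' @param band analysis band (Hz), default 10-200 kHz.
#' @return frequency in kHz.
#' @export
peak_frequency <- function(spec, band = ANALYSIS_BAND_HZ) {
  idx <- band_index(spec, band)
  p <- spec$power[idx]
  if (all(p == 0)) stop("zero spectrum in analysis band")
  spec$frequencies[idx[which.max(p)]] / 1000
}

#' Centroid frequency, kHz
#'
#' Power-weighted mean frequency over the analysis band.
#'
#' @inheritParams peak_frequency
#' @return frequency in kHz.
#' @export
centroid_frequency <- function(spec, band = ANALYSIS_BAND_HZ) {
  idx <- band_index(spec, band)
  s <- spec$power[idx]; f <- spec$frequencies[idx]
  tot <- sum(s)
  if (tot <= 0) stop("zero spectrum in analysis band")
  sum(f * s) / tot / 1000
}

#' RMS bandwidth, kHz
#'
#' Power-weighted standard deviation of frequency about the centroid.
#'
#' @inheritParams peak_frequency
#' @return bandwidth in kHz.
#' @export
rms_bandwidth <- function(spec, band = ANALYSIS_BAND_HZ) {
  idx <- band_index(spec, band)
  s <- spec$power[idx]; f <- spec$frequencies[idx]
  tot <- sum(s)
  if (tot <= 0) stop("zero spectrum in analysis band")
  fc <- sum(f * s) / tot
  sqrt(sum((f - fc)^2 * s) / tot) / 1000
}

#' -3 dB / -10 dB bandwidth and lower cut-off frequency, kHz
#'
#' Threshold on the power spectrum at `drop` dB below the peak
#' (-3 dB = half power, -10 dB = one-tenth power). The band edges are the
#' outermost threshold crossings within the analysis band — the lowest- and
#' highest-frequency crossings — with linear interpolation between bins, so
#' a notched spectrum does not truncate the band. If the spectrum never
#' drops below the threshold inside the analysis band the result spans the
#' whole band and is flagged.
#'
#' @param spec a `ClickSpectrum`.
#' @param drop threshold below peak, dB (3 or 10).
#' @param band analysis band (Hz).
#' @return list with `bandwidth_khz`, `lower_khz`, `upper_khz`, `flagged`.
#' @export
db_bandwidth <- function(spec, drop, band = ANALYSIS_BAND_HZ) {
  idx <- band_index(spec, band)
  p <- spec$power[idx]; f <- spec$frequencies[idx]
  if (all(p == 0)) stop("zero spectrum in analysis band")
  thr <- max(p) * 10^(-drop / 10)
  above <- which(p >= thr)
  i1 <- above[1]; i2 <- above[length(above)]
  flagged <- FALSE
  lower <- if (i1 > 1) {
    f[i1 - 1] + (thr - p[i1 - 1]) / (p[i1] - p[i1 - 1]) * (f[i1] - f[i1 - 1])
  } else { flagged <- TRUE; f[1] }
  upper <- if (i2 < length(p)) {
    f[i2] + (thr - p[i2]) / (p[i2 + 1] - p[i2]) * (f[i2 + 1] - f[i2])
  } else { flagged <- TRUE; f[length(f)] }
  list(bandwidth_khz = (upper - lower) / 1000,
       lower_khz = lower / 1000, upper_khz = upper / 1000,
       flagged = flagged)
}

#' All eight parameters of one click
#'
#' Assembles the full parameter record for a (retained) click candidate:
#' the -10 dB duration from the interpolated envelope and the seven
#' spectral parameters from the interpolated 32-point power spectrum.
#'
#' @param click a `ClickCandidate`.
#' @param rec the source `AudioRecording`.
#' @param species,session_id,train_id provenance stamped on the row.
#' @param band spectral analysis band (Hz).
#' @return one-row data frame: `species`, `session_id`, `train_id` and the
#'   eight [click_parameters()] columns.
#' @export
extract_features <- function(click, rec, species = NA_character_,
                             session_id = NA_character_,
                             train_id = NA_character_,
                             band = ANALYSIS_BAND_HZ) {
  win <- extract_window(rec, click$time_index)
  if (all(win$samples == 0)) stop("zero-amplitude click window")
  spec <- click_spectrum(win)
  b3 <- db_bandwidth(spec, 3, band)
  b10 <- db_bandwidth(spec, 10, band)
  data.frame(
    species = species, session_id = session_id, train_id = train_id,
    duration_us = duration_minus10dB(win),
    peak_khz = peak_frequency(spec, band),
    centroid_khz = centroid_frequency(spec, band),
    lower3_khz = b3$lower_khz,
    lower10_khz = b10$lower_khz,
    bw3_khz = b3$bandwidth_khz,
    bw10_khz = b10$bandwidth_khz,
    bwrms_khz = rms_bandwidth(spec, band),
    stringsAsFactors = FALSE)
}

#' Feature table for the highest-amplitude click of each qualified train
#'
#' @param trains list of `ClickTrain` (only qualified ones are used).
#' @param rec the source `AudioRecording`.
#' @param species species label for the table.
#' @return data frame, one row per qualified train.
#' @export
extract_feature_table <- function(trains, rec, species = NA_character_) {
  rows <- lapply(trains, function(tr) {
    if (!isTRUE(tr$qualified)) return(NULL)
    best <- select_highest_amplitude(tr)
    extract_features(best, rec, species = species,
                     session_id = tr$session_id, train_id = tr$train_id)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
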