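#' Spectral energy detector configuration
#'
#' Settings of the impulse detector. A recording is cut into short segments
#' (default 5 ms); each segment gets a Welch-averaged power spectrum
#' (Hanning window, default 576-point FFT, 50% overlap — 1 kHz bins at the
#' nominal 576 kHz rate). A segment is flagged as containing a click
#' candidate when at least `bin_fraction` (default 13%) of the frequency
#' bins between `band_low` and `band_high` (default 15-95 kHz, inclusive)
#' exceed the noise floor by more than `snr_threshold` dB (default 15 dB).
#'
#' Candidates are then screened: spectral peak below `min_peak_frequency`
#' (default 20 kHz; vessel noise and other low-frequency transients) or
#' amplitude above `clip_fraction` of the recorder's full scale (default
#' 80%; clipped clicks) mark a false positive.
#'
#' @param segment_length segment duration in seconds (default 0.005).
#' @param fft_size Welch sub-frame / FFT length in samples (default 576).
#' @param overlap_fraction sub-frame overlap (default 0.5).
#' @param snr_threshold per-bin SNR threshold in dB (default 15).
#' @param band_low,band_high detection band edges in Hz (default 15000, 95000).
#' @param bin_fraction minimum fraction of band bins above threshold (default 0.13).
#' @param min_peak_frequency false-positive spectral-peak floor in Hz (default 20000).
#' @param clip_fraction false-positive amplitude ceiling as a fraction of
#'   full scale (default 0.8).
#' @param min_separation minimum envelope-peak separation within a merged
#'   flagged region, seconds (default 0.001).
#' @return a `DetectorConfig` list.
#' @export
detector_config <- function(segment_length = 0.005, fft_size = 576,
                            overlap_fraction = 0.5, snr_threshold = 15,
                            band_low = 15000, band_high = 95000,
                            bin_fraction = 0.13, min_peak_frequency = 20000,
                            clip_fraction = 0.8, min_separation = 0.001) {
  stopifnot(bin_fraction > 0, bin_fraction <= 1,
            band_low < band_high,
            overlap_fraction > 0, overlap_fraction < 1)
  structure(list(segment_length = segment_length, fft_size = as.integer(fft_size),
                 overlap_fraction = overlap_fraction,
                 snr_threshold = snr_threshold,
                 band_low = band_low, band_high = band_high,
                 bin_fraction = bin_fraction,
                 min_peak_frequency = min_peak_frequency,
                 clip_fraction = clip_fraction,
                 min_separation = min_separation),
            class = "DetectorConfig")
}

# One-sided power spectra of frames given as columns of a matrix, one
# spectrum per frame. Scaling: the sum of a frame's one-sided spectrum
# equals its mean squared value up to window noise gain (Parseval).
frame_spectra_onesided <- function(frames, window) {
  n <- length(window)
  X <- stats::mvfft(frames * window)
  p2 <- Mod(X)^2 / (n * sum(window^2))    # two-sided, per frame
  half <- n %/% 2
  one <- p2[1:(half + 1), , drop = FALSE]
  one[2:half, ] <- 2 * one[2:half, ]
  one
}

#' Welch segment spectra of a recording
#'
#' Cuts the recording into `segment_length` segments and computes one
#' averaged power spectrum per segment from Hanning-windowed,
#' `overlap_fraction`-overlapped sub-frames of `fft_size` samples (about
#' ten sub-frames per 5 ms segment at 576 kHz). Sub-frames are laid out
#' continuously over the whole recording and averaged into the segment
#' containing their centre, so a click falling on a segment boundary is
#' never lost in the window taper of an edge-aligned sub-frame. An
#' incomplete segment at the recording tail is discarded, as partial Welch
#' averaging would bias the SNR criterion.
#'
#' @param rec an `AudioRecording` (normally band-pass filtered first).
#' @param cfg a [detector_config()].
#' @return a `SegmentSpectra` object: list with `frequencies` (Hz, one-sided
#'   bin grid), `power` (bins x segments matrix), `segment_starts` (1-based
#'   first sample of each segment), `segment_samples`, `sample_rate`.
#' @export
segment_spectra <- function(rec, cfg = detector_config()) {
  stopifnot(inherits(rec, "AudioRecording"))
  fs <- rec$sample_rate
  seg_n <- round(cfg$segment_length * fs)
  nfft <- cfg$fft_size
  if (seg_n < nfft)
    stop("segment_length shorter than one FFT frame at this sample rate")
  n <- length(rec$samples)
  nseg <- n %/% seg_n
  half <- nfft %/% 2
  freqs <- (0:half) * fs / nfft
  if (nseg < 1) {
    warning("recording shorter than one segment; no spectra computed")
    return(structure(list(frequencies = freqs,
                          power = matrix(0, half + 1, 0),
                          segment_starts = integer(0),
                          segment_samples = seg_n, sample_rate = fs),
                     class = "SegmentSpectra"))
  }
  hop <- round(nfft * (1 - cfg$overlap_fraction))
  w <- signal::hanning(nfft)
  frame_starts <- seq(1, nseg * seg_n - nfft + 1, by = hop)
  centers <- frame_starts + (nfft - 1) / 2
  seg_of <- pmin(nseg, (ceiling(centers) - 1) %/% seg_n + 1)
  power <- matrix(0, half + 1, nseg)
  counts <- integer(nseg)
  chunk <- 4000L
  for (c0 in seq(1, length(frame_starts), by = chunk)) {
    sel <- c0:min(length(frame_starts), c0 + chunk - 1)
    idx <- outer(0:(nfft - 1), frame_starts[sel], "+")
    sp <- frame_spectra_onesided(matrix(rec$samples[idx], nrow = nfft), w)
    for (j in seq_along(sel)) {
      s <- seg_of[sel[j]]
      power[, s] <- power[, s] + sp[, j]
      counts[s] <- counts[s] + 1L
    }
  }
  power <- sweep(power, 2, pmax(counts, 1L), "/")
  structure(list(frequencies = freqs, power = power,
                 segment_starts = as.integer((0:(nseg - 1)) * seg_n + 1),
                 segment_samples = as.integer(seg_n), sample_rate = fs),
            class = "SegmentSpectra")
}

#' Noise floor for the per-bin SNR criterion
#'
#' The per-bin noise reference is a low quantile (default 20th percentile)
#' of each bin's power across all segments of the recording; the quantile
#' is robust to sparse click contamination, which raises only the upper
#' tail of the per-bin power distribution. Because a Welch power estimate
#' is chi-squared distributed, a low quantile sits systematically below the
#' mean noise power; the estimator removes this bias by a self-calibrating
#' chi-squared correction — the dispersion (ratio of the low quantile to
#' the per-bin median) determines the equivalent degrees of freedom, and
#' the quantile is rescaled to the corresponding mean. Degenerate input
#' (identical segments) has no dispersion and gets no correction.
#'
#' @param spectra a [segment_spectra()] result.
#' @param probs quantile used as the noise floor (default 0.2).
#' @return a `NoiseSpectrum`: list with `frequencies` and `power`.
#' @export
estimate_noise_spectrum <- function(spectra, probs = 0.2) {
  stopifnot(inherits(spectra, "SegmentSpectra"))
  if (ncol(spectra$power) < 5)
    stop("need at least 5 segments to estimate a noise spectrum")
  qlo <- apply(spectra$power, 1, stats::quantile, probs = probs, names = FALSE)
  qmed <- apply(spectra$power, 1, stats::median)
  ok <- qmed > 0
  ratio <- if (any(ok)) stats::median(qlo[ok] / qmed[ok]) else 1
  corr <- 1
  if (is.finite(ratio) && ratio < 0.995 && ratio > 0) {
    f <- function(lnu) {
      nu <- exp(lnu)
      stats::qchisq(probs, nu) / stats::qchisq(0.5, nu) - ratio
    }
    nu <- tryCatch(exp(stats::uniroot(f, c(log(0.5), log(1e6)))$root),
                   error = function(e) Inf)
    if (is.finite(nu)) corr <- nu / stats::qchisq(probs, nu)
  }
  structure(list(frequencies = spectra$frequencies, power = qlo * corr),
            class = "NoiseSpectrum")
}

#' Click candidate
#'
#' @param time_index 1-based sample index of the envelope peak.
#' @param peak_amplitude envelope peak amplitude (uPa).
#' @param sample_rate sampling rate (Hz), used to derive `time_s`.
#' @param segment_index index of the detection segment (NA if hand-built).
#' @param waveform raw samples around the click (for spectral screening).
#' @param flags character vector of rejection reasons (empty if clean).
#' @return a `ClickCandidate` list.
#' @export
click_candidate <- function(time_index, peak_amplitude, sample_rate,
                            segment_index = NA_integer_, waveform = NULL,
                            flags = character(0)) {
  stopifnot(time_index >= 1, peak_amplitude >= 0)
  structure(list(time_index = as.integer(time_index),
                 time_s = (time_index - 1) / sample_rate,
                 peak_amplitude = peak_amplitude,
                 sample_rate = sample_rate,
                 segment_index = as.integer(segment_index),
                 waveform = waveform, flags = flags),
            class = "ClickCandidate")
}

#' Detect click candidates with the per-bin SNR criterion
#'
#' A segment is flagged when the number of bins in
#' `[band_low, band_high]` (edges inclusive) whose power exceeds the noise
#' floor by more than `snr_threshold` dB reaches
#' `ceiling(bin_fraction * n_band_bins)` (81 bins and a minimum of 11 at the
#' defaults). Runs of consecutive flagged segments are merged — an
#' echolocation click lasts tens of microseconds and can straddle a segment
#' boundary — and each merged region yields one candidate per local envelope
#' maximum, maxima at least `min_separation` apart and above four times the
#' region's median envelope.
#'
#' @param rec the (band-pass filtered) `AudioRecording`.
#' @param cfg a [detector_config()].
#' @param noise a [estimate_noise_spectrum()] result on the same bin grid.
#' @param spectra optional precomputed [segment_spectra()] (recomputed if NULL).
#' @return list of `ClickCandidate` objects, time-ordered.
#' @export
detect_candidates <- function(rec, cfg = detector_config(), noise,
                              spectra = NULL) {
  stopifnot(inherits(rec, "AudioRecording"), inherits(noise, "NoiseSpectrum"))
  if (is.null(spectra)) spectra <- segment_spectra(rec, cfg)
  if (!isTRUE(all.equal(spectra$frequencies, noise$frequencies)))
    stop("noise spectrum is not on the segment-spectrum bin grid")
  nseg <- ncol(spectra$power)
  if (nseg == 0) return(list())
  in_band <- spectra$frequencies >= cfg$band_low &
             spectra$frequencies <= cfg$band_high
  need <- ceiling(cfg$bin_fraction * sum(in_band) - 1e-9)
  thr_lin <- 10^(cfg$snr_threshold / 10)
  npow <- noise$power[in_band]
  flagged <- vapply(seq_len(nseg), function(s) {
    p <- spectra$power[in_band, s]
    above <- (npow > 0 & p > thr_lin * npow) | (npow == 0 & p > 0)
    sum(above) >= need
  }, logical(1))
  if (!any(flagged)) return(list())

  seg_n <- spectra$segment_samples
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cands <- list()
  min_sep <- max(1L, round(cfg$min_separation * rec$sample_rate))
  for (r in which(runs$values)) {
    s0 <- spectra$segment_starts[starts[r]]
    s1 <- min(spectra$segment_starts[ends[r]] + seg_n - 1, length(rec$samples))
    env <- envelope(rec$samples[s0:s1])
    floor_amp <- 4 * stats::median(env)
    remaining <- env
    repeat {
      i <- which.max(remaining)
      a <- remaining[i]
      if (!is.finite(a) || a <= floor_amp || a <= 0) break
      t_idx <- s0 + i - 1
      w0 <- max(1, t_idx - 64); w1 <- min(length(rec$samples), t_idx + 64)
      cands[[length(cands) + 1]] <- click_candidate(
        time_index = t_idx, peak_amplitude = env[i],
        sample_rate = rec$sample_rate,
        segment_index = (t_idx - 1) %/% seg_n + 1,
        waveform = rec$samples[w0:w1])
      mask <- max(1, i - min_sep):min(length(remaining), i + min_sep)
      remaining[mask] <- -Inf
    }
  }
  cands[order(vapply(cands, `[[`, 1, "time_index"))]
}

#' Remove false-positive candidates
#'
#' Drops candidates whose click-spectrum peak frequency is below
#' `min_peak_frequency` (flag `"low_peak_frequency"`) and candidates whose
#' amplitude exceeds `clip_fraction` of the recorder's full-scale pressure
#' (flag `"clipped"`). Idempotent; never increases the candidate count.
#'
#' @param cands list of `ClickCandidate`.
#' @param cfg a [detector_config()].
#' @param rec the source `AudioRecording` (for the full-scale pressure and,
#'   when a candidate carries no waveform, the click samples).
#' @return the retained candidates; the dropped ones, with their flags set,
#'   are attached as `attr(, "rejected")`.
#' @export
remove_false_positives <- function(cands, cfg = detector_config(), rec) {
  stopifnot(inherits(rec, "AudioRecording"))
  pfs <- full_scale_pressure(rec)
  kept <- list(); rejected <- list()
  for (cand in cands) {
    flags <- character(0)
    wf <- cand$waveform
    if (is.null(wf)) {
      w0 <- max(1, cand$time_index - 64)
      w1 <- min(length(rec$samples), cand$time_index + 64)
      wf <- rec$samples[w0:w1]
    }
    win <- click_window(wf, cand$sample_rate)
    spec <- click_spectrum(win)
    fp_khz <- peak_frequency(spec, band = c(0, Inf))
    if (is.finite(fp_khz) && fp_khz * 1000 < cfg$min_peak_frequency)
      flags <- c(flags, "low_peak_frequency")
    amp <- max(cand$peak_amplitude, max(abs(wf)))
    if (amp > cfg$clip_fraction * pfs)
      flags <- c(flags, "clipped")
    if (length(flags)) {
      cand$flags <- union(cand$flags, flags)
      rejected[[length(rejected) + 1]] <- cand
    } else {
      kept[[length(kept) + 1]] <- cand
    }
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Highest-amplitude click of a train
#'
#' With a single hydrophone it cannot be known whether a click was recorded
#' on the animal's acoustic axis; the standard surrogate is the highest
#' amplitude click of each train. Ties break to the earliest click.
#'
#' @param train a `ClickTrain` (or a plain list of `ClickCandidate`).
#' @return the selected `ClickCandidate`.
#' @export
select_highest_amplitude <- function(train) {
  clicks <- if (inherits(train, "ClickTrain")) train$clicks else train
  if (!length(clicks)) stop("empty click train")
  amps <- vapply(clicks, `[[`, 1, "peak_amplitude")
  times <- vapply(clicks, `[[`, 1, "time_index")
  ord <- order(-amps, times)
  clicks[[ord[1]]]
}

#' Candidate list as a data frame
#'
#' @param cands list of `ClickCandidate`.
#' @param source_id recording identifier to stamp on each row.
#' @return data frame with columns `source_id`, `time_s`,
#'   `peak_amplitude_uPa`, `segment_index`, `flags`.
#' @export
candidates_table <- function(cands, source_id = "") {
  data.frame(
    source_id = source_id,
    time_s = vapply(cands, `[[`, 1, "time_s"),
    peak_amplitude_uPa = vapply(cands, `[[`, 1, "peak_amplitude"),
    segment_index = vapply(cands, `[[`, 1L, "segment_index"),
    flags = vapply(cands, function(x) paste(x$flags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
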