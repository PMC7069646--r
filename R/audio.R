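#' Calibrated single-channel recording
#'
#' Container for a hydrophone recording converted to absolute sound pressure.
#' Autonomous recorders report a full-scale level: the peak sound pressure
#' (dB re 1 uPa) that maps to digital full scale. Samples here are stored in
#' micropascal so that amplitude rules (e.g. the clipping filter) can be
#' expressed against the recorder's capability.
#'
#' @param samples numeric vector of pressure samples (uPa).
#' @param sample_rate sampling rate in Hz.
#' @param full_scale_level peak full-scale calibration, dB re 1 uPa.
#'   Default 173, the SoundTrap 202HF high-gain setting.
#' @param source_id free-text identifier (file name, deployment id).
#' @param start_time optional POSIXct start time.
#'
#' @return An object of class `AudioRecording`: a list with fields
#'   `samples`, `sample_rate`, `full_scale_level`, `source_id`, `start_time`.
#' @export
audio_recording <- function(samples, sample_rate, full_scale_level = 173,
                            source_id = "", start_time = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (length(samples) && any(!is.finite(samples)))
    stop("samples must be finite")
  pfs <- 10^(full_scale_level / 20)
  if (length(samples) && max(abs(samples)) > pfs * (1 + 1e-9))
    stop("samples exceed the pressure equivalent of full_scale_level")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         full_scale_level = full_scale_level, source_id = source_id,
         start_time = start_time),
    class = "AudioRecording")
}

#' Full-scale pressure of a recording
#'
#' @param rec an `AudioRecording` (or a full-scale level in dB re 1 uPa).
#' @return peak pressure (uPa) corresponding to digital full scale.
#' @export
full_scale_pressure <- function(rec) {
  fsl <- if (inherits(rec, "AudioRecording")) rec$full_scale_level else rec
  10^(fsl / 20)
}

#' @export
print.AudioRecording <- function(x, ...) {
  cat(sprintf("AudioRecording '%s': %d samples @ %g kHz (%.3f s), full scale %g dB re 1 uPa\n",
              x$source_id, length(x$samples), x$sample_rate / 1000,
              length(x$samples) / x$sample_rate, x$full_scale_level))
  invisible(x)
}

#' @export
length.AudioRecording <- function(x) length(x$samples)

# ---- RIFF/WAV I/O -----------------------------------------------------------
# Minimal mono WAV support: PCM 16-bit (format code 1) and IEEE float32
# (format code 3). Chunk-walking reader so files with extra chunks (LIST,
# fact, ...) are handled.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        code      = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("WAV file missing fmt/data chunk: ", path)
  fmt$data <- data
  fmt
}

#' Read a mono WAV file as a calibrated recording
#'
#' Accepts PCM 16-bit or IEEE float32 mono WAV. Digital samples are
#' normalized to \[-1, 1\] and scaled to pressure:
#' `pressure = normalized * 10^(full_scale_level/20)` uPa.
#'
#' @param path path to a mono WAV file.
#' @param full_scale_level full-scale calibration in dB re 1 uPa (default 173).
#' @return An [audio_recording()].
#' @export
read_recording <- function(path, full_scale_level = 173) {
  if (!file.exists(path)) stop("file not found: ", path)
  w <- read_wav_raw(path)
  if (w$channels != 1)
    stop("only mono WAV is supported; file has ", w$channels, " channels")
  norm <- if (w$code == 1 && w$bits == 16) {
    readBin(w$data, "integer", length(w$data) / 2, 2, endian = "little") / 32768
  } else if (w$code == 3 && w$bits == 32) {
    readBin(w$data, "double", length(w$data) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV format (code ", w$code, ", ", w$bits, " bit); ",
         "expected PCM16 or float32")
  }
  if (!length(norm)) stop("zero-length audio: ", path)
  audio_recording(norm * 10^(full_scale_level / 20), w$rate,
                  full_scale_level = full_scale_level,
                  source_id = basename(path))
}

#' Write a recording to a mono WAV file
#'
#' Pressure samples are normalized by the recording's full-scale pressure and
#' written as PCM 16-bit (default) or IEEE float32.
#'
#' @param rec an `AudioRecording`.
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "AudioRecording"))
  norm <- rec$samples / full_scale_pressure(rec)
  norm <- pmin(1, pmax(-1, norm))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(norm)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                    # mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(8 * bytes_per), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    counts <- as.integer(pmin(32767, pmax(-32768, round(norm * 32768))))
    writeBin(counts, con, 2, endian = "little")
  } else {
    writeBin(norm, con, 4, endian = "little")
  }
  invisible(path)
}

# ---- Band-pass preprocessing ------------------------------------------------

#' Butterworth band-pass specification
#'
#' The preprocessing filter applied to every recording before detection:
#' a 4th-order Butterworth band pass, 10-200 kHz by default, removing
#' whistles, low-frequency vessel noise and out-of-band energy.
#'
#' @param low_cut lower band edge (Hz), default 10000.
#' @param high_cut upper band edge (Hz), default 200000.
#' @param order filter order, default 4.
#' @return a `FilterSpec` list.
#' @export
filter_spec <- function(low_cut = 10000, high_cut = 200000, order = 4) {
  if (low_cut <= 0 || high_cut <= low_cut)
    stop("need 0 < low_cut < high_cut")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), family = "butterworth-bandpass"),
            class = "FilterSpec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the filter forward and backward ([signal::filtfilt()]) so click
#' timing (inter-click intervals, envelope peaks) is not skewed by group
#' delay; the effective magnitude response is the square of the one-pass
#' Butterworth response (twice the attenuation in dB). `high_cut` is clamped
#' to 0.99 x Nyquist so the stage is usable at sample rates where the
#' nominal 200 kHz edge would be above Nyquist.
#'
#' @param rec an `AudioRecording`.
#' @param spec a [filter_spec()].
#' @return a filtered `AudioRecording` of the same length and rate.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "AudioRecording"), inherits(spec, "FilterSpec"))
  nyq <- rec$sample_rate / 2
  hi <- min(spec$high_cut, 0.99 * nyq)
  lo <- spec$low_cut
  if (lo >= hi) stop("low_cut >= clamped high_cut at this sample rate")
  bf <- signal::butter(spec$order, c(lo, hi) / nyq, type = "pass")
  out <- signal::filtfilt(bf, rec$samples)
  r <- rec
  # zero-phase filtering can ring marginally past full scale; tolerate it
  r$samples <- out
  class(r) <- "AudioRecording"
  r
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Squared-magnitude response of the digital Butterworth band-pass at given
#' frequencies, in dB, for one pass or for the zero-phase forward-backward
#' application (`passes = 2`). Used as an oracle for filter behaviour.
#'
#' @param freq frequencies (Hz).
#' @param spec a [filter_spec()].
#' @param sample_rate sampling rate (Hz).
#' @param passes 1 for single-pass, 2 for filtfilt.
#' @return response in dB (0 = unity gain).
#' @export
butter_response_db <- function(freq, spec, sample_rate, passes = 2) {
  nyq <- sample_rate / 2
  hi <- min(spec$high_cut, 0.99 * nyq)
  bf <- signal::butter(spec$order, c(spec$low_cut, hi) / nyq, type = "pass")
  h <- vapply(freq, function(f) {
    zk <- exp(-1i * 2 * pi * f / sample_rate * (seq_along(bf$b) - 1))
    abs(sum(bf$b * zk) / sum(bf$a * zk))
  }, 1)
  passes * 20 * log10(pmax(h, 1e-300))
}
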