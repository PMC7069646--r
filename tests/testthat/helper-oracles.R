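# Independent oracles used across the tests. Everything here is written
# directly from definitions (dense summation, enumeration, closed forms),
# deliberately not reusing the package's computation paths.

# Gabor click synthesized straight from its formula.
oracle_gabor <- function(fc_khz, sigma_us, fs, amp = 1, pad = 200) {
  sigma <- sigma_us * 1e-6
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  x <- amp * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * fc_khz * 1000 * t)
  list(samples = c(numeric(pad), x, numeric(pad)),
       peak_index = pad + half + 1)
}

# Hand-built spectrum object on an arbitrary grid (for closed-form cases).
oracle_spectrum <- function(frequencies, power, fs = 576000) {
  structure(list(frequencies = frequencies, power = power,
                 amplitude = sqrt(power), sample_rate = fs,
                 interp_factor = 10),
            class = "ClickSpectrum")
}

# Brute-force weighted moments over bins (plain loops, no vectorized reuse).
oracle_centroid_khz <- function(spec, band = c(10000, 200000)) {
  num <- 0; den <- 0
  for (i in seq_along(spec$frequencies)) {
    f <- spec$frequencies[i]
    if (f >= band[1] && f <= band[2]) {
      num <- num + f * spec$power[i]
      den <- den + spec$power[i]
    }
  }
  num / den / 1000
}

oracle_rms_bw_khz <- function(spec, band = c(10000, 200000)) {
  fc <- oracle_centroid_khz(spec, band) * 1000
  num <- 0; den <- 0
  for (i in seq_along(spec$frequencies)) {
    f <- spec$frequencies[i]
    if (f >= band[1] && f <= band[2]) {
      num <- num + (f - fc)^2 * spec$power[i]
      den <- den + spec$power[i]
    }
  }
  sqrt(num / den) / 1000
}

# Dense direct DFT (plain summation) of a Hanning-windowed 32-sample click:
# the independent route to the interpolated click spectrum.
oracle_windowed_power <- function(samples, fs, freqs) {
  n <- length(samples)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- samples * w
  vapply(freqs, function(f) {
    ph <- -2i * pi * f * (0:(n - 1)) / fs
    s <- sum(xw * exp(ph))
    2 * Mod(s)^2 / (n * sum(w^2))
  }, 1)
}

# Exact two-sided Mann-Whitney p-value by enumerating all label
# assignments of the pooled sample.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Match detected candidate times against truth times within a tolerance.
oracle_recall <- function(truth_times, cand_times, tol_s = 5e-4) {
  if (!length(truth_times)) return(NA_real_)
  mean(vapply(truth_times,
              function(t) any(abs(cand_times - t) < tol_s), TRUE))
}

# Shared small fixture: one rendered scene reused by several tests.
scene_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trains <- lapply(1:3, function(i)
        train_model(10, mean_ici = 0.04, start_time = 0.1 + (i - 1) * 0.7,
                    snr_db = 30, center_khz = c(95, 70, 85)[i],
                    species = c("A", "B", "A")[i]))
      cache <<- render_scene(scene_spec(2.2, trains, seed = 11, shrimp_rate = 1))
    }
    cache
  }
})
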