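# Independent oracles used across the suite. These deliberately avoid the
# package's own signal path: direct convolution sums, linear-interpolation
# periodograms, and brute-force entropy counting.

# Direct O(n*k) convolution of an impulse train with the analytic Bateman
# IRF; independent of the package's recursive-filter implementation.
oracle_edr_trace <- function(times, amps, tau1, tau2, fs, duration, tonic = 0) {
  tt <- (seq_len(ceiling(duration * fs) + 1L) - 1) / fs
  y <- rep(tonic, length(tt))
  for (k in seq_along(times)) {
    t0 <- tt[round(times[k] * fs) + 1L]   # same grid snap as the generator
    dtk <- tt - t0
    y <- y + amps[k] * ifelse(dtk > 0, exp(-dtk / tau1) - exp(-dtk / tau2), 0)
  }
  y
}

# Periodogram of the RR sequence itself: linear interpolation of (beat time,
# rr) pairs onto a uniform 4 Hz grid, then a raw periodogram. Independent of
# resample_berger / welch_psd.
oracle_rr_periodogram <- function(beat_times, fs_out = 4) {
  rr <- diff(beat_times)
  tt <- seq(beat_times[1], beat_times[length(beat_times) - 1], by = 1 / fs_out)
  x <- approx(beat_times[-length(beat_times)], rr, xout = tt)$y
  x <- x - mean(x)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs_out), plot = FALSE,
                          taper = 0, detrend = TRUE)
  data.frame(freq = sp$freq, spec = sp$spec)
}

oracle_band_fraction <- function(pg, lo, hi) {
  sum(pg$spec[pg$freq >= lo & pg$freq < hi]) / sum(pg$spec)
}

# Brute-force approximate entropy with explicit double loops.
oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    cnt <- numeric(nv)
    for (i in 1:nv) {
      c_i <- 0
      for (j in 1:nv) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) c_i <- c_i + 1
      }
      cnt[i] <- c_i / nv
    }
    mean(log(cnt))
  }
  phi(m) - phi(m + 1)
}

# Match detected event times to ground truth: TP when within tol seconds.
match_events <- function(detected, truth, tol = 0.05) {
  tp <- sum(vapply(truth, function(b) any(abs(detected - b) <= tol), logical(1)))
  list(tp = tp,
       sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

grab_empty_for_test <- function() {
  tibble::tibble(time = numeric(), duration = numeric(), peak_flexion = numeric())
}

# Magnitude response of an N-point moving average at frequency f (Hz).
oracle_maf_gain <- function(f, N, fs) {
  abs(sin(pi * f * N / fs) / (N * sin(pi * f / fs)))
}

# A quick modulated synthetic ECG at a given SNR (dB), returning trace+truth.
make_noisy_ecg <- function(seed, duration = 120, snr_db = 10, mean_hr = 70) {
  rr <- generate_rr_series(duration, mean_hr,
                           modulators = data.frame(freq = 0.25, amp = 0.02),
                           noise_sd = 0.01, seed = seed)
  ecg <- synthesize_ecg(rr, fs = 250)
  noise_sd <- sqrt(mean(ecg$value^2) / 10^(snr_db / 10))
  set.seed(seed + 7000)
  ecg$value <- ecg$value + rnorm(nrow(ecg), 0, noise_sd)
  attr(ecg, "fs") <- 250
  list(ecg = ecg, beats = rr$beat_times)
}
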