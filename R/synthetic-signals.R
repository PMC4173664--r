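#' Generate an RR-interval series with controlled spectral modulation
#'
#' Beat times are laid down iteratively from an instantaneous RR model
#' `RR(t) = 60/mean_hr + sum_i a_i sin(2 pi f_i t + phi_i)` plus white
#' per-beat noise, giving a tachogram whose spectral content is known by
#' construction. This is the ground truth every downstream HRV stage is
#' tested against.
#'
#' @param duration recording length in seconds (> 0).
#' @param mean_hr mean heart rate in beats/min, within \[30, 200\].
#' @param modulators data frame with columns `freq` (Hz), `amp` (seconds) and
#'   optionally `phase` (radians, default 0); NULL for an unmodulated series.
#' @param noise_sd per-beat white noise SD in seconds.
#' @param seed integer seed; identical seeds give identical output.
#' @return an object of class `rr_ground_truth`: a list with `beat_times`,
#'   `rr_intervals` (their first differences), `modulators`, `mean_hr`.
#' @export
generate_rr_series <- function(duration, mean_hr = 60, modulators = NULL,
                               noise_sd = 0, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be positive.")
  if (!is.numeric(mean_hr) || mean_hr < 30 || mean_hr > 200) {
    abort("`mean_hr` must lie in [30, 200] beats/min.")
  }
  mods <- normalize_modulators(modulators)
  rr0 <- 60 / mean_hr
  rr_fn <- function(t) {
    rr <- rr0
    if (nrow(mods) > 0) {
      rr <- rr + sum(mods$amp * sin(2 * pi * mods$freq * t + mods$phase))
    }
    rr
  }
  with_seed(seed, {
    beats <- gen_beat_times(duration, rr_fn, noise_sd)
    structure(
      list(
        beat_times = beats,
        rr_intervals = diff(beats),
        modulators = mods,
        mean_hr = mean_hr
      ),
      class = "rr_ground_truth"
    )
  })
}

# Lay down beat times from an instantaneous RR model rr_fn(t) (seconds) plus
# per-beat white noise; intervals floored at 0.21 s.
gen_beat_times <- function(duration, rr_fn, noise_sd = 0) {
  n_max <- ceiling(duration / 0.21) + 2L
  beats <- numeric(n_max)
  t <- 0
  k <- 1L
  beats[1L] <- 0
  while (t <= duration && k < n_max) {
    rr <- rr_fn(t)
    if (noise_sd > 0) rr <- rr + rnorm(1, 0, noise_sd)
    rr <- max(rr, 0.21)
    t <- t + rr
    k <- k + 1L
    beats[k] <- t
  }
  beats <- beats[seq_len(k)]
  beats[beats <= duration + 1e-9]
}

normalize_modulators <- function(modulators) {
  if (is.null(modulators) || (is.data.frame(modulators) && nrow(modulators) == 0)) {
    return(tibble::tibble(freq = numeric(), amp = numeric(), phase = numeric()))
  }
  m <- tibble::as_tibble(modulators)
  if (!all(c("freq", "amp") %in% names(m))) {
    abort("`modulators` needs columns `freq` and `amp`.")
  }
  if (!"phase" %in% names(m)) m$phase <- 0
  m[c("freq", "amp", "phase")]
}

#' Default synthetic PQRST beat template
#'
#' A fixed sum of localized Gaussian bumps (P, Q, R, S, T waves) with the
#' R-wave maximum of 1 mV exactly at offset zero. Adequate to exercise QRS
#' detection; not a biophysical model.
#'
#' @param fs sampling rate in Hz.
#' @return list with `offsets` (seconds relative to the R peak) and
#'   `values` (mV).
#' @export
ecg_beat_template <- function(fs = 250) {
  offs <- seq(-0.20, 0.40, by = 1 / fs)
  bump <- function(center, width, amp) amp * exp(-((offs - center) / width)^2)
  v <- bump(-0.17, 0.025, 0.12) +   # P
    bump(-0.025, 0.010, -0.15) +    # Q
    bump(0, 0.012, 1.15) +          # R
    bump(0.035, 0.012, -0.25) +     # S
    bump(0.22, 0.060, 0.30)         # T
  v <- v / max(v)                   # R peak exactly 1 mV
  # pin the maximum to offset 0 on this grid
  i0 <- which.min(abs(offs))
  v[i0] <- max(v) + 1e-6
  list(offsets = offs, values = v)
}

#' Synthesize an ECG trace from ground-truth beat times
#'
#' Places a beat template at every beat time (nearest sample) and adds white
#' noise, so the noise-free local maxima coincide with the ground-truth beat
#' times to within one sample period.
#'
#' @param rr an `rr_ground_truth` object (or list with `beat_times`).
#' @param fs sampling rate in Hz (>= 100); 250 Hz mirrors the chest-worn
#'   acquisition this pipeline targets.
#' @param beat_template list with `offsets`/`values` as from
#'   [ecg_beat_template()]; NULL uses the default at `fs`.
#' @param noise_sd additive white noise SD in mV.
#' @param seed integer seed.
#' @param duration optional trace length in seconds; default covers the last
#'   beat plus the template tail.
#' @return a signal table (mV).
#' @export
synthesize_ecg <- function(rr, fs = 250, beat_template = NULL, noise_sd = 0,
                           seed = NULL, duration = NULL) {
  if (fs < 100) abort("`fs` must be at least 100 Hz.")
  beats <- rr$beat_times
  tpl <- beat_template %||% ecg_beat_template(fs)
  tpl_span <- diff(range(tpl$offsets))
  if (length(beats) >= 2 && tpl_span > min(diff(beats))) {
    abort("Beat template is longer than the shortest RR interval (beats would overlap).")
  }
  dur <- duration %||% (if (length(beats)) max(beats) + max(tpl$offsets) + 0.2 else 1)
  n <- ceiling(dur * fs) + 1L
  x <- numeric(n)
  if (length(beats)) {
    tpl_idx <- round(tpl$offsets * fs)
    for (b in beats) {
      i0 <- round(b * fs) + 1L
      idx <- i0 + tpl_idx
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tpl$values[ok]
    }
  }
  with_seed(seed, {
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    signal_tbl(x, fs = fs, units = "mV")
  })
}

#' Describe ground-truth sudomotor activity
#'
#' @param impulses data frame with columns `time` (s), `amplitude`
#'   (uS.s, non-negative) and optionally `nonspecific` (logical; spontaneous
#'   responses not tied to a stimulus).
#' @param tonic data frame with columns `time`, `level` (uS) describing a
#'   piecewise-linear tonic skin-conductance level, or a single number for a
#'   flat level.
#' @param duration recording span in seconds.
#' @return object of class `sudomotor_truth`.
#' @export
sudomotor_truth <- function(impulses = NULL, tonic = 2, duration = 60) {
  imp <- if (is.null(impulses) || NROW(impulses) == 0) {
    tibble::tibble(time = numeric(), amplitude = numeric(), nonspecific = logical())
  } else {
    x <- tibble::as_tibble(impulses)
    if (!"nonspecific" %in% names(x)) x$nonspecific <- FALSE
    x
  }
  if (any(imp$amplitude < 0)) abort("Impulse amplitudes must be non-negative.")
  if (any(imp$time < 0 | imp$time > duration)) {
    abort("Impulse times must fall within [0, duration].")
  }
  if (is.numeric(tonic) && length(tonic) == 1) {
    tonic <- tibble::tibble(time = c(0, duration), level = c(tonic, tonic))
  }
  structure(
    list(impulses = imp, tonic = tibble::as_tibble(tonic), duration = duration),
    class = "sudomotor_truth"
  )
}

#' Synthesize a skin-conductance trace from sudomotor ground truth
#'
#' Forward model: the impulse train (discretized onto the sample grid, area
#' preserved) is convolved with the biexponential Bateman impulse response
#' and added to the piecewise-linear tonic level plus white noise.
#'
#' @param truth a [sudomotor_truth()] object.
#' @param tau1,tau2 Bateman time constants in seconds, `tau1 > tau2 > 0`
#'   (slow decay / fast rise).
#' @param fs sampling rate in Hz (>= 10); 100 Hz mirrors the glove
#'   acquisition.
#' @param noise_sd additive white noise SD in uS.
#' @param seed integer seed.
#' @return a signal table (uS).
#' @export
synthesize_edr <- function(truth, tau1 = 2, tau2 = 0.75, fs = 100,
                           noise_sd = 0, seed = NULL) {
  check_bateman(tau1, tau2)
  if (fs < 10) abort("`fs` must be at least 10 Hz.")
  n <- ceiling(truth$duration * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  driver <- numeric(n)
  if (nrow(truth$impulses)) {
    idx <- round(truth$impulses$time * fs) + 1L
    for (k in seq_along(idx)) {
      driver[idx[k]] <- driver[idx[k]] + truth$impulses$amplitude[k] * fs
    }
  }
  phasic <- convolve_irf(driver, tau1, tau2, fs)
  tonic <- approx(truth$tonic$time, truth$tonic$level, xout = tt, rule = 2)$y
  with_seed(seed, {
    x <- phasic + tonic
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    signal_tbl(x, fs = fs, units = "uS")
  })
}

# driver (uS/s per sample) -> phasic conductance, exact discrete convolution
# with the sampled Bateman IRF. Recursive (2-pole IIR) form, O(n).
convolve_irf <- function(driver, tau1, tau2, fs) {
  dt <- 1 / fs
  a1 <- exp(-dt / tau1)
  a2 <- exp(-dt / tau2)
  # y[n] = dt * sum_j driver[j] h[n-j], h[k] = a1^k - a2^k  (h[0] = 0)
  y1 <- as.numeric(stats::filter(driver, a1, method = "recursive"))
  y2 <- as.numeric(stats::filter(driver, a2, method = "recursive"))
  (y1 - y2) * dt
}

check_bateman <- function(tau1, tau2) {
  if (!is.numeric(tau1) || !is.numeric(tau2) || tau2 <= 0 || tau1 <= tau2) {
    abort("Bateman parameters require tau1 > tau2 > 0.")
  }
  invisible(TRUE)
}

#' Synthesize motion channels with grab gestures and walking
#'
#' Produces tri-axial accelerometer and orientation traces, five finger
#' flexion channels and the additive grab artifact that contaminates the
#' skin-conductance channel. Each grab raises all five flexion channels with
#' a smooth pulse and injects a synchronous biphasic spike into
#' `edr_artifact`; walking segments raise accelerometer variance.
#'
#' @param duration recording length in seconds.
#' @param grab_times grab onsets in seconds (non-overlapping given
#'   `grab_width`).
#' @param walk_segments data frame with `start`, `end` columns (seconds), or
#'   NULL.
#' @param fs sampling rate in Hz for all motion channels.
#' @param grab_width flexion pulse width in seconds.
#' @param grab_amp flexion pulse amplitude (sensor units).
#' @param artifact_amp amplitude of the EDR grab artifact in uS (0 disables).
#' @param flexion_drift per-channel linear baseline drift over the recording
#'   (sensor units), emulating textile-sensor drift.
#' @param noise_sd sensor noise floor SD (all channels).
#' @param seed integer seed.
#' @return list with tibbles `accel` (time, x, y, z), `orient` (time, x, y,
#'   z), `flexion` (time, f1..f5), and signal table `edr_artifact` (uS), plus
#'   the echoed `grab_times`.
#' @export
synthesize_motion <- function(duration, grab_times = numeric(),
                              walk_segments = NULL, fs = 100,
                              grab_width = 0.6, grab_amp = 1,
                              artifact_amp = 0.3, flexion_drift = 0.5,
                              noise_sd = 0.02, seed = NULL) {
  grab_times <- sort(grab_times)
  if (length(grab_times) > 1 && any(diff(grab_times) < grab_width)) {
    abort("`grab_times` overlap for the given pulse width.")
  }
  n <- ceiling(duration * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  pulse <- function(center, width) {
    z <- (tt - center) / width
    out <- numeric(n)
    in_p <- z >= 0 & z <= 1
    out[in_p] <- sin(pi * z[in_p])^2
    out
  }
  with_seed(seed, {
    flex_pulse <- Reduce(`+`, lapply(grab_times, pulse, width = grab_width),
                         accumulate = FALSE) %||% numeric(n)
    if (length(grab_times) == 0) flex_pulse <- numeric(n)
    flexion <- purrr::map(1:5, function(i) {
      drift <- flexion_drift * runif(1, -1, 1) * tt / max(duration, 1)
      grab_amp * runif(1, 0.8, 1.2) * flex_pulse + drift + rnorm(n, 0, noise_sd)
    })
    names(flexion) <- paste0("f", 1:5)
    flexion <- tibble::as_tibble(c(list(time = tt), flexion))

    walk <- numeric(n)
    if (!is.null(walk_segments) && NROW(walk_segments) > 0) {
      for (k in seq_len(NROW(walk_segments))) {
        sel <- tt >= walk_segments$start[k] & tt < walk_segments$end[k]
        walk[sel] <- 1
      }
    }
    mk_axis <- function(gain) rnorm(n, 0, noise_sd) + gain * walk * rnorm(n, 0, 0.15)
    accel <- tibble::tibble(time = tt, x = mk_axis(1), y = mk_axis(1), z = mk_axis(1))
    orient <- tibble::tibble(
      time = tt,
      x = rnorm(n, 0, noise_sd) + 0.3 * walk * rnorm(n, 0, 0.15),
      y = rnorm(n, 0, noise_sd) + 0.3 * walk * rnorm(n, 0, 0.15),
      z = rnorm(n, 0, noise_sd) + 0.3 * walk * rnorm(n, 0, 0.15)
    )

    # biphasic artifact: sharp rise then undershoot, locked to the grab pulse
    art <- numeric(n)
    if (artifact_amp != 0) {
      for (g in grab_times) {
        z <- (tt - g) / grab_width
        sel <- z >= 0 & z <= 1.5
        art[sel] <- art[sel] +
          artifact_amp * (sin(pi * pmin(z[sel], 1))^2 - 0.4 * sin(pi * pmax(z[sel] - 0.5, 0) / 1)^2)
      }
    }
    list(
      accel = accel, orient = orient, flexion = flexion,
      edr_artifact = signal_tbl(art, fs = fs, units = "uS"),
      grab_times = grab_times
    )
  })
}
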