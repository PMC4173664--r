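#' Zero-phase low-pass filtering of a skin-conductance trace
#'
#' Forward-and-reverse Butterworth filtering (no net phase shift, unit DC
#' gain), the standard pre-processing step before continuous decomposition.
#'
#' @param edr signal table (uS).
#' @param cutoff cutoff frequency in Hz (default 2, must be below Nyquist).
#' @param order Butterworth order for each pass.
#' @return filtered signal table.
#' @export
lowpass_zero_phase <- function(edr, cutoff = 2, order = 4) {
  fs <- signal_fs(edr)
  if (cutoff >= fs / 2) abort("`cutoff` must be below the Nyquist frequency.")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  x <- edr$value
  n <- length(x)
  # odd (point-mirror) extension keeps the forward-reverse pass free of edge
  # transients on finite recordings
  npad <- min(n - 1L, ceiling(10 * fs / cutoff))
  xp <- c(2 * x[1] - x[(npad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  out <- edr
  out$value <- yp[npad + seq_len(n)]
  attr(out, "fs") <- fs
  attr(out, "units") <- attr(edr, "units")
  out
}

#' Bateman impulse response function
#'
#' The biexponential unitary SCR shape
#' `IRF(t) = (exp(-t/tau1) - exp(-t/tau2)) u(t)` with slow decay `tau1` and
#' fast rise `tau2`. Zero for `t <= 0`, positive for `t > 0`, vanishing as
#' `t -> Inf`, with maximum at `tau1 tau2 / (tau1 - tau2) * log(tau1/tau2)`.
#'
#' @param t time in seconds (vectorized).
#' @param tau1,tau2 time constants in seconds, `tau1 > tau2 > 0`.
#' @return response values (dimensionless shape).
#' @export
bateman_irf <- function(t, tau1 = 2, tau2 = 0.75) {
  check_bateman(tau1, tau2)
  ifelse(t > 0, exp(-t / tau1) - exp(-t / tau2), 0)
}

#' Decompose skin conductance into tonic and phasic driver components
#'
#' Continuous decomposition by exact discrete deconvolution: the sampled
#' Bateman impulse response is a two-pole recursive system, so its inverse
#' is a three-tap FIR filter applied to the trace. The tonic share of the
#' raw driver is estimated from driver-quiet anchor sections (one anchor per
#' `tonic_grid` seconds, interpolated by a smooth spline) and subtracted; the
#' remainder is the phasic driver (clipped at the negativity tolerance). The
#' tonic conductance component is reconstructed as the input minus the
#' reconvolved phasic driver, so tonic + driver (*) IRF reproduces the input
#' exactly up to the clipped negativity.
#'
#' A sudomotor impulse of area `a` uS.s appears in the phasic driver as a
#' pulse integrating to `a` (driver units are uS/s).
#'
#' @param edr signal table (uS), low-pass filtered (see
#'   [lowpass_zero_phase()]); at least `10 * tau1` seconds long.
#' @param tau1,tau2 Bateman time constants (seconds).
#' @param tonic_grid anchor spacing for the tonic estimate (seconds).
#' @param driver_smooth width (seconds) of the zero-phase, unit-area Hann
#'   smoother applied to the raw driver; inverse filtering amplifies
#'   residual high-frequency noise roughly as f^2, and this averaging
#'   suppresses it while preserving impulse areas and peak times. Set 0 to
#'   disable.
#' @param negativity_tol phasic driver values above `-negativity_tol *
#'   max(driver)` are treated as numerical noise and clipped to zero.
#' @return object of class `edr_decomposition`: list with `signal` (tibble
#'   time, edr, tonic, driver, phasic), `scr_events` (filled by
#'   [detect_scrs()]), `params`, `fs`, and `residual` summary.
#' @export
deconvolve_edr <- function(edr, tau1 = 2, tau2 = 0.75, tonic_grid = 10,
                           driver_smooth = 0.2, negativity_tol = 0.01) {
  check_bateman(tau1, tau2)
  fs <- signal_fs(edr)
  n <- nrow(edr)
  if (n / fs < 10 * tau1) {
    abort(sprintf("Recording must be at least 10*tau1 = %.0f s long.", 10 * tau1))
  }
  dt <- 1 / fs
  a1 <- exp(-dt / tau1)
  a2 <- exp(-dt / tau2)
  y <- edr$value

  # exact inverse of the sampled IRF: d[k] = u[k+1] / (dt (a1-a2)),
  # u = y * (1 - (a1+a2) z^-1 + a1 a2 z^-2)
  u <- y - (a1 + a2) * c(0, head(y, -1)) + a1 * a2 * c(0, 0, head(y, -2))
  q <- c(u[-1], u[n]) / (dt * (a1 - a2))
  q[1:2] <- q[3]            # edge samples carry filter start-up transients
  q[n] <- q[n - 1]
  if (driver_smooth > 0) {
    kw <- max(3L, round(driver_smooth * fs) %/% 2L * 2L + 1L)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, kw - 1) / (kw - 1))
    w <- w / sum(w)
    half <- kw %/% 2L
    padded <- c(rev(q[seq_len(half) + 1L]), q, rev(q[n - seq_len(half)]))
    q <- as.numeric(stats::filter(padded, w, sides = 2))[half + seq_len(n)]
  }

  # tonic share of the driver: spline through driver-quiet anchors
  med <- median(q)
  madv <- mad(q, constant = 1.4826)
  quiet <- abs(q - med) <= pmax(3 * madv, 1e-12)
  anchors_t <- seq(edr$time[1], edr$time[n], by = tonic_grid)
  anchor_val <- vapply(anchors_t, function(a) {
    sel <- quiet & abs(edr$time - a) <= tonic_grid / 2
    if (any(sel)) median(q[sel]) else med
  }, numeric(1))
  qt <- if (length(anchors_t) >= 4) {
    sp <- stats::smooth.spline(anchors_t, anchor_val, spar = 0.6)
    predict(sp, edr$time)$y
  } else {
    approx(anchors_t, anchor_val, xout = edr$time, rule = 2)$y
  }

  driver <- q - qt
  # filter start-up transients: no phasic attribution in the first/last 2 s
  edge_n <- min(n, round(2 * fs))
  driver[seq_len(edge_n)] <- 0
  driver[n - seq_len(edge_n) + 1L] <- 0

  # noise gate: driver noise scale from the fast residual around a running
  # median; only excursions whose peak clears 4 sigma count as sudomotor
  # activity (sigma = 0 on noise-free input, so nothing is gated there)
  kq <- max(3L, round(1 * fs) %/% 2L * 2L + 1L)
  sigma <- mad(q - runmed(q, min(kq, n %/% 2L * 2L + 1L)))
  neg_floor <- -negativity_tol * max(driver, dt)
  clipped_frac <- mean(driver < neg_floor)
  if (sigma > 0) {
    keep <- rep(FALSE, n)
    above <- driver > 3 * sigma
    runs <- true_runs(above)
    if (nrow(runs)) {
      lowf <- 0.5 * sigma
      for (i in seq_len(nrow(runs))) {
        i0 <- runs$start_idx[i]
        i1 <- runs$end_idx[i]
        if (max(driver[i0:i1]) <= 4 * sigma) next
        while (i0 > 1L && driver[i0 - 1L] > lowf) i0 <- i0 - 1L
        while (i1 < n && driver[i1 + 1L] > lowf) i1 <- i1 + 1L
        keep[i0:i1] <- TRUE
      }
    }
    driver[!keep] <- 0
  }
  driver[driver < 0] <- 0                 # non-negative phasic driver
  phasic <- convolve_irf(driver, tau1, tau2, fs)
  tonic <- y - phasic
  sig <- tibble::tibble(time = edr$time, edr = y, tonic = tonic,
                        driver = driver, phasic = phasic)
  out <- structure(
    list(
      signal = sig,
      scr_events = NULL,
      params = list(tau1 = tau1, tau2 = tau2, tonic_grid = tonic_grid,
                    driver_smooth = driver_smooth,
                    negativity_tol = negativity_tol),
      fs = fs,
      residual = list(
        max_abs = 0,                       # reconstruction is exact by design
        negativity_clipped_frac = clipped_frac
      )
    ),
    class = "edr_decomposition"
  )
  out$scr_events <- detect_scrs(out)
  out
}

#' Detect significant skin-conductance responses in a decomposition
#'
#' Segments the phasic driver into impulse clusters (runs above a small
#' driver floor, split at deep interior minima), reconvolves each cluster
#' with the IRF and keeps those whose reconvolved amplitude exceeds
#' `min_amplitude`.
#'
#' @param decomp an `edr_decomposition`.
#' @param min_amplitude significance threshold on the reconvolved response
#'   amplitude (uS).
#' @return tibble of events: `onset_time`, `peak_time`, `amplitude` (uS),
#'   `driver_area` (uS.s).
#' @export
detect_scrs <- function(decomp, min_amplitude = 0.01) {
  sig <- decomp$signal
  fs <- decomp$fs
  dt <- 1 / fs
  d <- sig$driver
  empty <- tibble::tibble(onset_time = numeric(), peak_time = numeric(),
                          amplitude = numeric(), driver_area = numeric())
  if (all(d <= 0)) return(empty)
  floor_d <- max(d) * 1e-3
  runs <- true_runs(d > floor_d)
  if (nrow(runs) == 0) return(empty)

  irf_max <- max(bateman_irf(seq(0, 10 * decomp$params$tau1, by = dt),
                             decomp$params$tau1, decomp$params$tau2))
  events <- list()
  for (k in seq_len(nrow(runs))) {
    i0 <- runs$start_idx[k]
    i1 <- runs$end_idx[k]
    seg <- d[i0:i1]
    # split at interior minima below a quarter of the smaller flanking peak
    pk <- local_maxima(seg, min_dist = max(1L, round(0.3 * fs)))
    if (length(pk) == 0) pk <- which.max(seg)
    bounds <- c(1L)
    if (length(pk) > 1) {
      for (p in seq_len(length(pk) - 1L)) {
        valley_rel <- pk[p] + which.min(seg[pk[p]:pk[p + 1]]) - 1L
        if (seg[valley_rel] < 0.25 * min(seg[pk[p]], seg[pk[p + 1]])) {
          bounds <- c(bounds, valley_rel)
        }
      }
    }
    bounds <- unique(c(bounds, length(seg) + 1L))
    for (b in seq_len(length(bounds) - 1L)) {
      j0 <- i0 + bounds[b] - 1L
      j1 <- i0 + bounds[b + 1L] - 2L
      sub <- d[j0:j1]
      area <- sum(sub) * dt
      amp <- area * irf_max       # amplitude of the reconvolved single response
      if (amp >= min_amplitude) {
        events[[length(events) + 1L]] <- tibble::tibble(
          onset_time = sig$time[j0],
          peak_time = sig$time[j0 + which.max(sub) - 1L],
          amplitude = amp,
          driver_area = area
        )
      }
    }
  }
  if (length(events) == 0) return(empty)
  dplyr::bind_rows(events) |> dplyr::arrange(.data$onset_time)
}

#' Phasic features within a response window
#'
#' Event-related skin-conductance features for a window following a stimulus
#' onset: count of SCRs with onsets in `[window_start + min_latency,
#' window_start + window_len]` (nSCR), latency of the first such response
#' relative to the window start (Lat), sum of their reconvolved amplitudes
#' (AmpSum), plus driver-level statistics over the window: time integral
#' divided by window length (Mean_SCR), variance (Var_SCR), area under the
#' driver (AUC_SCR) and maximum (Max_SCR).
#'
#' @param decomp an `edr_decomposition` with detected events.
#' @param window_start stimulus onset in seconds.
#' @param window_len response-window length in seconds (<= 5 conventionally).
#' @param min_latency earliest admissible response onset after the window
#'   start (seconds); earlier responses never contribute.
#' @param mask optional `artifact_mask` ([build_artifact_mask()]): events
#'   with masked onsets and masked driver samples are excluded, implementing
#'   the gesture-artifact exclusion rule.
#' @return one-row tibble: `nSCR`, `Lat`, `AmpSum`, `Mean_SCR`, `Var_SCR`,
#'   `AUC_SCR`, `Max_SCR`.
#' @export
phasic_features <- function(decomp, window_start, window_len = 5,
                            min_latency = 0, mask = NULL) {
  sig <- decomp$signal
  if (window_start < sig$time[1] - 1e-9 ||
      window_start + window_len > tail(sig$time, 1) + 1e-9) {
    abort("Response window falls outside the recording.")
  }
  ev <- decomp$scr_events
  inw <- ev[ev$onset_time >= window_start + min_latency &
              ev$onset_time <= window_start + window_len, , drop = FALSE]
  if (!is.null(mask) && nrow(inw)) {
    masked_on <- vapply(inw$onset_time, function(t0) {
      any(t0 >= mask$spans$start & t0 <= mask$spans$end)
    }, logical(1))
    inw <- inw[!masked_on, , drop = FALSE]
  }
  sel <- sig$time >= window_start & sig$time <= window_start + window_len
  if (!is.null(mask)) {
    mm <- approx(mask$time, as.numeric(mask$mask), xout = sig$time,
                 method = "constant", rule = 2)$y
    sel <- sel & mm < 0.5
  }
  d <- sig$driver[sel]
  dt <- 1 / decomp$fs
  tibble::tibble(
    nSCR = nrow(inw),
    Lat = if (nrow(inw)) inw$onset_time[1] - window_start else NA_real_,
    AmpSum = sum(inw$amplitude),
    Mean_SCR = sum(d) * dt / window_len,
    Var_SCR = if (length(d) > 1) var(d) else 0,
    AUC_SCR = sum(d) * dt,
    Max_SCR = if (length(d)) max(d) else 0
  )
}

#' Tonic features and non-specific response count
#'
#' Mean and variance of the decomposed tonic component over the recording,
#' plus the number of non-specific responses: detected SCRs whose onsets
#' fall outside every stimulus response window.
#'
#' @param decomp an `edr_decomposition`.
#' @param stimulus_windows data frame with `start`, `end` columns (seconds);
#'   NULL treats every response as non-specific.
#' @return one-row tibble: `Mean_Tonic`, `Var_Tonic`, `NSR`.
#' @export
tonic_features <- function(decomp, stimulus_windows = NULL) {
  tonic <- decomp$signal$tonic
  ev <- decomp$scr_events
  nsr <- if (is.null(stimulus_windows) || NROW(stimulus_windows) == 0) {
    nrow(ev)
  } else {
    w <- tibble::as_tibble(stimulus_windows)
    inside <- vapply(ev$onset_time, function(t0) {
      any(t0 >= w$start & t0 <= w$end)
    }, logical(1))
    sum(!inside)
  }
  tibble::tibble(
    Mean_Tonic = mean(tonic),
    Var_Tonic = var(tonic),
    NSR = nsr
  )
}
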