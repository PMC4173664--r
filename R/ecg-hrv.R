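#' Remove ECG baseline wander with a moving-average filter
#'
#' Subtracts a centered running mean from the trace, removing slow drift
#' (respiration-scale wander) while sparing the QRS complex. The default
#' 0.6 s window attenuates components slower than about 1 Hz.
#'
#' @param ecg signal table (mV).
#' @param window running-mean window in seconds; must span at least 3
#'   samples.
#' @return baseline-corrected signal table.
#' @export
remove_baseline_maf <- function(ecg, window = 0.6) {
  fs <- signal_fs(ecg)
  k <- round(window * fs)
  if (!is.numeric(window) || window <= 0 || k < 3) {
    abort("`window` must be positive and span at least 3 samples.")
  }
  n <- nrow(ecg)
  if (k >= n) {
    base <- rep(mean(ecg$value), n)     # degenerate window: global mean
  } else {
    # centered running mean with shrinking edges (cumulative-sum form)
    half <- k %/% 2
    cs <- cumsum(c(0, ecg$value))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    base <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out <- ecg
  out$value <- ecg$value - base
  attr(out, "fs") <- fs
  attr(out, "units") <- attr(ecg, "units")
  out
}

#' Pan-Tompkins QRS detection
#'
#' The classic detection chain: 5-15 Hz band-pass, differentiation, squaring,
#' 150 ms moving-window integration, adaptive signal/noise thresholds with
#' search-back, and a 200 ms refractory period. Detected peaks are localized
#' on the baseline-corrected input signal.
#'
#' @param ecg signal table (mV), sampled at >= 100 Hz, at least 3 s long.
#' @param bandpass low/high band edges in Hz.
#' @param integration_window moving-window integration length in seconds.
#' @param refractory minimum peak separation in seconds.
#' @param search_back enable threshold-halving search-back for missed beats.
#' @return numeric vector of R-peak times in seconds (empty, with a warning,
#'   when no QRS-like activity is found).
#' @export
detect_qrs_pan_tompkins <- function(ecg, bandpass = c(5, 15),
                                    integration_window = 0.150,
                                    refractory = 0.200,
                                    search_back = TRUE) {
  fs <- signal_fs(ecg)
  if (fs < 100) abort("QRS detection needs `fs` >= 100 Hz.")
  n <- nrow(ecg)
  if (n / fs < 3) abort("QRS detection needs at least 3 s of signal.")
  x <- remove_baseline_maf(ecg, window = 0.6)$value

  if (all(abs(x) < 1e-12) || sd(x) == 0) {
    warn("No QRS-like activity found; returning an empty peak list.")
    return(numeric())
  }

  bp <- signal::butter(2, bandpass / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  der <- as.numeric(stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  wi <- max(3L, round(integration_window * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- round(refractory * fs)
  cand <- local_maxima(mwi, min_dist = refr, min_height = max(mwi) * 1e-4)
  if (length(cand) == 0) {
    warn("No QRS-like activity found; returning an empty peak list.")
    return(numeric())
  }

  # adaptive thresholding over candidate peaks
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  qrs_idx <- integer()
  rr_buf <- numeric()
  last_q <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    pk <- mwi[i]
    accepted <- FALSE
    if (pk > thr && (i - last_q) > refr) {
      accepted <- TRUE
    } else if (search_back && length(qrs_idx) >= 2) {
      rr_ave <- mean(tail(rr_buf, 8))
      if ((i - last_q) > 1.66 * rr_ave && pk > thr / 2 && (i - last_q) > refr) {
        accepted <- TRUE
      }
    }
    if (accepted) {
      spki <- 0.125 * pk + 0.875 * spki
      if (length(qrs_idx)) rr_buf <- c(rr_buf, i - last_q)
      qrs_idx <- c(qrs_idx, i)
      last_q <- i
    } else {
      npki <- 0.125 * pk + 0.875 * npki
    }
  }
  if (length(qrs_idx) == 0) {
    warn("No peaks exceeded the adaptive threshold; returning an empty peak list.")
    return(numeric())
  }

  # localize the R wave on the baseline-corrected signal near each MWI peak
  half <- as.integer(round(0.10 * fs))
  r_idx <- vapply(qrs_idx, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(n, as.integer(i) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce the refractory period on the localized peaks (keep the larger)
  if (length(r_idx) > 1) {
    keep <- rep(TRUE, length(r_idx))
    for (k in 2:length(r_idx)) {
      prev <- max(which(keep[1:(k - 1)]))
      if (r_idx[k] - r_idx[prev] < refr) {
        if (x[r_idx[k]] > x[r_idx[prev]]) keep[prev] <- FALSE else keep[k] <- FALSE
      }
    }
    r_idx <- r_idx[keep]
  }
  ecg$time[r_idx]
}

#' RR series and sinus-beat (NN) selection from R-peak times
#'
#' RR intervals are first differences of the peak times; intervals deviating
#' by more than `tol` from the median of their `n_neighbors` surrounding
#' intervals are flagged non-sinus (ectopic or detection error) and excluded
#' from NN statistics.
#'
#' @param peak_times strictly increasing R-peak times in seconds (>= 2).
#' @param tol fractional deviation tolerance for the neighbor-median rule.
#' @param n_neighbors neighborhood size for the running median.
#' @return object of class `rr_series`: tibble with columns `onset` (interval
#'   start time), `rr` (seconds), `nn` (logical sinus flag), plus attribute
#'   `peak_times`.
#' @export
rr_from_peaks <- function(peak_times, tol = 0.2, n_neighbors = 5) {
  if (length(peak_times) < 2) abort("Need at least 2 peaks to form RR intervals.")
  if (any(diff(peak_times) <= 0)) abort("`peak_times` must be strictly increasing.")
  rr <- diff(peak_times)
  k <- max(3L, n_neighbors %/% 2L * 2L + 1L)
  ref <- if (length(rr) >= k) runmed(rr, k, endrule = "median") else rep(median(rr), length(rr))
  nn <- abs(rr - ref) <= tol * ref
  out <- tibble::tibble(onset = head(peak_times, -1), rr = rr, nn = nn)
  class(out) <- c("rr_series", class(out))
  attr(out, "peak_times") <- peak_times
  out
}

#' Uniformly resample an RR series (Berger tachogram)
#'
#' Berger's windowed beat-counting algorithm: at each output sample the local
#' heart period is estimated from the (fractional) number of RR intervals
#' falling inside a window of two output sampling periods, which keeps the
#' local mean rate of the resampled series equal to the instantaneous rate
#' implied by the beat times. Non-sinus intervals are replaced by the running
#' median before counting.
#'
#' @param rr an `rr_series` from [rr_from_peaks()].
#' @param out_rate output sampling rate in Hz (default 4).
#' @return signal table of RR values (seconds) sampled at `out_rate`.
#' @export
resample_berger <- function(rr, out_rate = 4) {
  if (out_rate <= 0) abort("`out_rate` must be positive.")
  stopifnot(inherits(rr, "rr_series") || all(c("onset", "rr") %in% names(rr)))
  if (sum(rr$nn %||% TRUE) < 2) abort("Need at least 2 NN intervals to resample.")
  rr_use <- rr$rr
  if (!is.null(rr$nn) && any(!rr$nn)) {
    ref <- if (length(rr_use) >= 5) runmed(rr_use, 5) else rep(median(rr_use), length(rr_use))
    rr_use[!rr$nn] <- ref[!rr$nn]
  }
  starts <- rr$onset
  ends <- rr$onset + rr_use
  span <- c(starts[1], max(ends))
  if (diff(span) < 2 / out_rate) abort("Beat span shorter than two output periods.")
  t_out <- seq(span[1], span[2], by = 1 / out_rate)
  w <- 1 / out_rate
  vals <- vapply(t_out, function(t0) {
    lo <- max(t0 - w, span[1])
    hi <- min(t0 + w, span[2])
    ov <- pmax(0, pmin(ends, hi) - pmax(starts, lo))
    cnt <- sum(ov / rr_use)
    if (cnt <= 0) return(NA_real_)
    # local heart period: window length over interval count
    (hi - lo) / cnt
  }, numeric(1))
  keep <- !is.na(vals)
  out <- signal_tbl(vals[keep], fs = out_rate, start = t_out[which(keep)[1]], units = "s")
  out
}
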