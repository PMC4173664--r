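#' Time-domain HRV statistics
#'
#' The statistical and morphological battery computed from a sequence of NN
#' (normal sinus) intervals: mean (MNN), SD (SDNN), standard error, root
#' mean square, mean/sum of squares, skewness, excess kurtosis, mean
#' absolute deviation, median, central moments of orders 2-4, successive-
#' difference measures (RMSSD, NN50, pNN50) and mean heart rate. Sample
#' (n-1) variance is used for SDNN/SEM; moments for skewness and kurtosis
#' are population (1/n) moments. Difference-based entries need at least 3
#' intervals and are NA below that.
#'
#' @param nn numeric vector of NN intervals in seconds (>= 2 values).
#' @return one-row tibble.
#' @export
time_domain_features <- function(nn) {
  nn <- as.numeric(nn)
  n <- length(nn)
  if (n < 2) abort("Need at least 2 NN intervals.")
  m <- mean(nn)
  m2 <- mean((nn - m)^2)
  m3 <- mean((nn - m)^3)
  m4 <- mean((nn - m)^4)
  d <- diff(nn)
  tibble::tibble(
    MNN = m,
    SDNN = sd(nn),
    SEM = sd(nn) / sqrt(n),
    RMS = sqrt(mean(nn^2)),
    mean_of_squares = mean(nn^2),
    sum_of_squares = sum(nn^2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis_excess = if (m2 > 0) m4 / m2^2 - 3 else NA_real_,
    MAD = mean(abs(nn - m)),
    median_nn = median(nn),
    moment2 = m2,
    moment3 = m3,
    moment4 = m4,
    RMSSD = if (length(d) >= 2) sqrt(mean(d^2)) else NA_real_,
    NN50 = if (length(d) >= 2) sum(abs(d) > 0.05) else NA_integer_,
    pNN50 = if (length(d) >= 2) 100 * sum(abs(d) > 0.05) / length(d) else NA_real_,
    HR_mean = mean(60 / nn),
    RRmean = m
  )
}

#' Geometric HRV features from the RR histogram
#'
#' The triangular index is the total interval count divided by the modal bin
#' count of the RR histogram; TINN is the base width `M - N` of the
#' least-squares triangular fit to the histogram (zero at `N` and `M`, peak
#' at the mode). The default 1/128 s bin width follows the short-term HRV
#' convention.
#'
#' @param nn NN intervals in seconds.
#' @param bin_width histogram bin width in seconds.
#' @return one-row tibble with `triangular_index` and `TINN` (seconds).
#' @export
geometric_features <- function(nn, bin_width = 1 / 128) {
  nn <- as.numeric(nn)
  if (length(nn) == 0) abort("Empty interval series.")
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  # bins anchored to the data minimum so the index is shift-invariant
  lo <- min(nn) - bin_width / 2
  breaks <- seq(lo, max(nn) + bin_width, by = bin_width)
  h <- graphics::hist(nn, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  peak <- which.max(counts)
  tri <- length(nn) / counts[peak]
  if (length(counts) < 2) {
    return(tibble::tibble(triangular_index = tri, TINN = bin_width))
  }

  # least-squares triangle over bin midpoints: zero at N and M, D(mode) at mode
  nb <- length(counts)
  best <- c(err = Inf, N = mids[1], M = mids[nb])
  d0 <- counts[peak]
  for (iN in 1:peak) {
    for (iM in peak:nb) {
      if (iN == iM) next
      q <- numeric(nb)
      upL <- if (peak > iN) seq(iN, peak) else peak
      q[upL] <- d0 * (mids[upL] - mids[iN]) / (mids[peak] - mids[iN] + 1e-12)
      if (iM > peak) {
        dn <- seq(peak, iM)
        q[dn] <- d0 * (mids[iM] - mids[dn]) / (mids[iM] - mids[peak] + 1e-12)
      }
      q[peak] <- d0
      err <- sum((counts - q)^2)
      if (err < best["err"]) best <- c(err = err, N = mids[iN], M = mids[iM])
    }
  }
  tinn <- if (is.finite(best[["err"]])) best[["M"]] - best[["N"]] else NA_real_
  tibble::tibble(triangular_index = tri, TINN = tinn)
}

#' Spectral HRV band powers
#'
#' Integrates a Welch PSD of the uniformly resampled tachogram over the
#' short-term HRV bands: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz,
#' plus the LF/HF balance ratio. Powers are in ms^2. A band is flagged
#' reliable only when the analysed span covers at least two cycles of its
#' lower edge; on 20-30 s windows the VLF (and usually LF) flags are FALSE,
#' the values are still reported.
#'
#' @param tachogram signal table of RR values in seconds, uniformly sampled
#'   (e.g. from [resample_berger()]).
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return one-row tibble: `VLF`, `LF`, `HF` (ms^2), `LF_HF_ratio`, and
#'   logical `*_reliable` flags.
#' @export
frequency_features <- function(tachogram,
                               bands = list(VLF = c(0.003, 0.04),
                                            LF = c(0.04, 0.15),
                                            HF = c(0.15, 0.4))) {
  fs <- signal_fs(tachogram)
  x <- tachogram$value * 1000      # seconds -> ms
  dur <- nrow(tachogram) / fs
  psd <- welch_psd(x, fs)
  pows <- lapply(bands, function(b) band_power(psd, b[1], b[2]))
  rel <- lapply(bands, function(b) dur >= 2 / b[1])
  lf <- pows$LF
  hf <- pows$HF
  out <- tibble::tibble(
    VLF = pows$VLF, LF = lf, HF = hf,
    LF_HF_ratio = if (!is.null(hf) && is.finite(hf) && hf > 0) lf / hf else NA_real_,
    VLF_reliable = rel$VLF, LF_reliable = rel$LF, HF_reliable = rel$HF
  )
  out
}

#' Poincare plot dispersions SD1 and SD2
#'
#' Short- and long-term variability of the lag-1 return map, under the
#' ellipse convention `SD1^2 = SDSD^2 / 2` and
#' `SD2^2 = 2 SDNN^2 - SDSD^2 / 2` (sample variances), which makes
#' `SD1^2 + SD2^2 = 2 var(nn)` an exact identity.
#'
#' @param nn NN intervals in seconds (>= 3).
#' @return one-row tibble with `SD1`, `SD2` (seconds).
#' @export
poincare_features <- function(nn) {
  nn <- as.numeric(nn)
  if (length(nn) < 3) abort("Need at least 3 intervals for the Poincare plot.")
  sdsd2 <- var(diff(nn))
  sdnn2 <- var(nn)
  sd1 <- sqrt(sdsd2 / 2)
  sd2 <- sqrt(max(0, 2 * sdnn2 - sdsd2 / 2))
  tibble::tibble(SD1 = sd1, SD2 = sd2)
}

#' Approximate entropy of an interval series
#'
#' Pincus' approximate entropy ApEn(m, r) with embedding dimension `m` and
#' tolerance equal to `r_frac` times the series SD (Chebyshev distance,
#' self-matches included). Perfectly regular series give 0; a degenerate
#' series (zero SD) is defined as 0.
#'
#' @param nn numeric series (>= 10 values recommended).
#' @param m embedding dimension (>= 1).
#' @param r_frac tolerance as a fraction of the series SD.
#' @return scalar entropy (dimensionless).
#' @export
entropy_feature <- function(nn, m = 2, r_frac = 0.2) {
  nn <- as.numeric(nn)
  n <- length(nn)
  if (m < 1) abort("`m` must be >= 1.")
  if (r_frac <= 0) abort("`r_frac` must be positive.")
  s <- sd(nn)
  if (!is.finite(s) || s == 0) return(0)
  r <- r_frac * s
  if (n < m + 2) return(NA_real_)
  phi <- function(mm) {
    nv <- n - mm + 1L
    emb <- sapply(seq_len(mm), function(j) nn[j:(j + nv - 1L)])
    if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
    # Chebyshev distances between all template pairs
    cnt <- vapply(seq_len(nv), function(i) {
      d <- abs(emb - matrix(emb[i, ], nv, mm, byrow = TRUE))
      dm <- if (mm == 1) d[, 1] else apply(d, 1, max)
      sum(dm <= r)
    }, numeric(1))
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

#' Full HRV feature battery for one analysis window
#'
#' Combines time-domain, geometric, spectral, Poincare and entropy features
#' for a single NN series. The tachogram for the spectral features is built
#' by Berger resampling at `resample_rate`.
#'
#' @param rr an `rr_series` (from [rr_from_peaks()]).
#' @param bin_width histogram bin width for the geometric features.
#' @param resample_rate tachogram rate in Hz.
#' @param entropy_m,entropy_r embedding and tolerance of the entropy
#'   feature.
#' @return one-row tibble with the complete battery (NA entries where a
#'   feature is undefined for the window).
#' @export
hrv_features <- function(rr, bin_width = 1 / 128, resample_rate = 4,
                         entropy_m = 2, entropy_r = 0.2) {
  nn <- rr$rr[rr$nn]
  if (length(nn) < 2) abort("Fewer than 2 NN intervals in the window.")
  td <- time_domain_features(nn)
  geo <- tryCatch(geometric_features(nn, bin_width),
                  error = function(e) tibble::tibble(triangular_index = NA_real_, TINN = NA_real_))
  fq <- tryCatch({
    tach <- resample_berger(rr, resample_rate)
    frequency_features(tach)
  }, error = function(e) tibble::tibble(
    VLF = NA_real_, LF = NA_real_, HF = NA_real_, LF_HF_ratio = NA_real_,
    VLF_reliable = FALSE, LF_reliable = FALSE, HF_reliable = FALSE
  ))
  pc <- tryCatch(poincare_features(nn),
                 error = function(e) tibble::tibble(SD1 = NA_real_, SD2 = NA_real_))
  ent <- tibble::tibble(entropy_E = entropy_feature(nn, entropy_m, entropy_r))
  dplyr::bind_cols(td, geo, fq, pc, ent)
}

#' HRV features over consecutive analysis windows
#'
#' Slices an RR series into the supplied windows and computes the full
#' battery per window. Windows shorter than 20 s are rejected: spectral and
#' variability estimates from shorter slices of a short-term recording are
#' not interpretable.
#'
#' @param rr an `rr_series` covering the recording.
#' @param windows data frame with `start`, `end` columns in seconds
#'   (non-overlapping).
#' @param ... forwarded to [hrv_features()].
#' @return tibble with one row per window (window bounds + features); rows
#'   with too few beats carry NA features.
#' @export
hrv_window_features <- function(rr, windows, ...) {
  windows <- tibble::as_tibble(windows)
  len <- windows$end - windows$start
  if (any(len < 20 - 1e-9)) {
    abort("HRV analysis windows must be at least 20 s long (short-term HRV constraint).")
  }
  if (nrow(windows) > 1) {
    o <- order(windows$start)
    if (any(windows$start[o][-1] < windows$end[o][-nrow(windows)] - 1e-9)) {
      abort("HRV analysis windows must not overlap.")
    }
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- rr$onset >= w$start & (rr$onset + rr$rr) <= w$end + 1e-9
    sub <- rr[sel, , drop = FALSE]
    class(sub) <- class(rr)
    attr(sub, "peak_times") <- c(sub$onset, tail(sub$onset + sub$rr, 1))
    feats <- if (sum(sub$nn) >= 2) {
      tryCatch(hrv_features(sub, ...), error = function(e) empty_hrv_row())
    } else {
      empty_hrv_row()
    }
    dplyr::bind_cols(tibble::tibble(window_start = w$start, window_end = w$end), feats)
  })
}

empty_hrv_row <- function() {
  tibble::tibble(
    MNN = NA_real_, SDNN = NA_real_, SEM = NA_real_, RMS = NA_real_,
    mean_of_squares = NA_real_, sum_of_squares = NA_real_, skewness = NA_real_,
    kurtosis_excess = NA_real_, MAD = NA_real_, median_nn = NA_real_,
    moment2 = NA_real_, moment3 = NA_real_, moment4 = NA_real_,
    RMSSD = NA_real_, NN50 = NA_integer_, pNN50 = NA_real_,
    HR_mean = NA_real_, RRmean = NA_real_,
    triangular_index = NA_real_, TINN = NA_real_,
    VLF = NA_real_, LF = NA_real_, HF = NA_real_, LF_HF_ratio = NA_real_,
    VLF_reliable = FALSE, LF_reliable = FALSE, HF_reliable = FALSE,
    SD1 = NA_real_, SD2 = NA_real_, entropy_E = NA_real_
  )
}
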