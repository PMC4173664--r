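#' Build a uniformly sampled signal table
#'
#' A signal trace is an ordinary tibble with a `time` column (seconds from
#' recording start) and a `value` column, uniformly sampled at `fs` Hz. The
#' sampling rate and units are stored as attributes so traces pipe through
#' dplyr verbs unharmed; [signal_fs()] falls back to the median time step when
#' the attribute has been dropped.
#'
#' @param value numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds.
#' @param units character unit label (e.g. "mV", "uS").
#' @return a tibble with columns `time`, `value` and attributes `fs`, `units`.
#' @export
signal_tbl <- function(value, fs, start = 0, units = NA_character_) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  n <- length(value)
  out <- tibble::tibble(
    time = start + (seq_len(n) - 1) / fs,
    value = as.numeric(value)
  )
  attr(out, "fs") <- fs
  attr(out, "units") <- units
  out
}

#' Sampling rate of a signal table
#'
#' @param x a tibble with a `time` column, ideally created by [signal_tbl()].
#' @return sampling rate in Hz.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  dt <- median(diff(x$time))
  if (!is.finite(dt) || dt <= 0) abort("Cannot infer a sampling rate from `time`.")
  1 / dt
}

#' Crop a signal table to a time window
#'
#' @param x signal table.
#' @param start,end window bounds in seconds, half-open `[start, end)`.
#' @return the cropped tibble (attributes preserved).
#' @export
signal_crop <- function(x, start, end) {
  keep <- x$time >= start & x$time < end
  out <- x[keep, , drop = FALSE]
  attr(out, "fs") <- attr(x, "fs")
  attr(out, "units") <- attr(x, "units")
  out
}

# Welch power spectral density with a Hann window.
#
# Returns a two-column tibble (freq, psd) with psd in units^2 per Hz, one-sided.
# seg_len = NULL uses a single segment spanning the whole series (a Hann-
# windowed periodogram), which is the right choice for the short 20-30 s
# windows this package analyses; longer series can ask for averaged segments
# with 50% overlap.
welch_psd <- function(x, fs, seg_len = NULL, detrend = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) abort("Need at least 4 samples for a PSD estimate.")
  if (detrend) {
    tt <- seq_len(n)
    x <- stats::residuals(stats::lm(x ~ tt))
  }
  if (is.null(seg_len) || seg_len >= n) seg_len <- n
  seg_len <- as.integer(seg_len)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  u <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    sp <- abs(fft(seg))^2 / (fs * u)
    half <- sp[seq_len(nf)]
    # fold power from negative frequencies (all but DC and Nyquist-if-even)
    fold <- if (seg_len %% 2L == 0L) 2L:(nf - 1L) else 2L:nf
    half[fold] <- 2 * half[fold]
    acc <- acc + half
  }
  psd <- acc / length(starts)
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / seg_len, psd = psd)
}

# Integrate a PSD table over [lo, hi) by the rectangle rule.
band_power <- function(psd_tbl, lo, hi) {
  df <- diff(psd_tbl$freq[1:2])
  sel <- psd_tbl$freq >= lo & psd_tbl$freq < hi
  sum(psd_tbl$psd[sel]) * df
}

# Indices of strict local maxima of x separated by at least min_dist samples
# (greedy, highest first).
local_maxima <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0 || min_dist <= 1L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in cand) {
    if (all(abs(i - taken) >= min_dist)) taken <- c(taken, i)
  }
  sort(taken)
}

# Runs of TRUE in a logical vector: tibble(start_idx, end_idx) (inclusive).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start_idx = starts[r$values], end_idx = ends[r$values])
}

# Set the RNG locally for a generator call; NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
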