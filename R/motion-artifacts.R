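#' Detect grab gestures from finger-flexion channels
#'
#' Adaptive-threshold detection robust to the slow baseline drift of textile
#' deformation sensors: per channel, the baseline is a running median
#' (`baseline_window` seconds) and a channel is active when it exceeds the
#' baseline by `k * MAD` of its baseline-corrected fluctuation. A grab event
#' is a run of at least `min_duration` seconds during which a majority
#' (>= `min_channels`) of the five channels are active.
#'
#' @param flexion tibble with a `time` column and five flexion channels
#'   (every non-time column is used); all channels share the sampling rate.
#' @param k threshold multiplier on the robust scale.
#' @param baseline_window running-median window in seconds.
#' @param min_channels channels that must be simultaneously active.
#' @param min_duration minimum event duration in seconds.
#' @param min_scale floor on the robust scale (sensor units), guarding
#'   against zero-variance channels.
#' @return tibble of `GrabEvent`s: `time` (onset), `duration`,
#'   `peak_flexion`.
#' @export
detect_grabs <- function(flexion, k = 6, baseline_window = 10,
                         min_channels = 3, min_duration = 0.2,
                         min_scale = 0.01) {
  chans <- setdiff(names(flexion), "time")
  if (length(chans) < min_channels) abort("Need at least `min_channels` flexion channels.")
  nlen <- vapply(flexion[chans], length, integer(1))
  if (length(unique(nlen)) != 1) abort("Flexion channels differ in length.")
  fs <- 1 / median(diff(flexion$time))
  kb <- max(3L, round(baseline_window * fs) %/% 2L * 2L + 1L)
  n <- nrow(flexion)
  active <- matrix(FALSE, n, length(chans))
  for (j in seq_along(chans)) {
    x <- flexion[[chans[j]]]
    base <- runmed(x, min(kb, n %/% 2L * 2L + 1L), endrule = "median")
    dev <- x - base
    sc <- max(mad(dev), min_scale)
    active[, j] <- dev > k * sc
  }
  maj <- rowSums(active) >= min_channels
  runs <- true_runs(maj)
  if (nrow(runs) == 0) return(grab_empty())
  runs$dur <- (runs$end_idx - runs$start_idx + 1L) / fs
  runs <- runs[runs$dur >= min_duration, , drop = FALSE]
  if (nrow(runs) == 0) return(grab_empty())
  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    sel <- runs$start_idx[i]:runs$end_idx[i]
    tibble::tibble(
      time = flexion$time[runs$start_idx[i]],
      duration = runs$dur[i],
      peak_flexion = max(as.matrix(flexion[sel, chans]))
    )
  })
}

grab_empty <- function() {
  tibble::tibble(time = numeric(), duration = numeric(), peak_flexion = numeric())
}

#' Movement activity indexes per analysis window
#'
#' The maximized acceleration index (MAI) is the sum of the per-axis
#' standard deviations of the tri-axial accelerometer inside a window
#' (sigma_x + sigma_y + sigma_z); the maximized rotation index (MRI) is the
#' analogous sum for the orientation channels. Windows must be at least
#' 20 s, matching the stimulus-presentation windows they quantify.
#'
#' @param accel,orient tibbles with `time`, `x`, `y`, `z` columns.
#' @param windows data frame with `start`, `end` columns in seconds.
#' @return tibble: `start`, `end`, `MAI`, `MRI`.
#' @export
activity_indexes <- function(accel, orient, windows) {
  windows <- tibble::as_tibble(windows)
  if (any(windows$end - windows$start < 20 - 1e-9)) {
    abort("Activity-index windows must be at least 20 s long.")
  }
  sum_sd <- function(df, w) {
    sel <- df$time >= w$start & df$time < w$end
    sum(vapply(c("x", "y", "z"), function(a) sd(df[[a]][sel]), numeric(1)))
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    tibble::tibble(start = w$start, end = w$end,
                   MAI = sum_sd(accel, w), MRI = sum_sd(orient, w))
  })
}

#' Build an artifact mask covering grab gestures
#'
#' Marks `[grab - pad_before, grab + duration + pad_after]` on the timeline
#' of a reference signal; overlapping padded spans are merged. The mask is
#' applied to the skin-conductance analysis only — chest-recorded ECG is not
#' affected by hand gestures and is never masked.
#'
#' @param grabs tibble of grab events ([detect_grabs()]).
#' @param timeline signal table whose `time` column defines the mask grid.
#' @param pad_before,pad_after padding in seconds (>= 0).
#' @return object of class `artifact_mask`: list with `mask` (logical per
#'   sample), `spans` (merged intervals with provenance), `time`.
#' @export
build_artifact_mask <- function(grabs, timeline, pad_before = 1, pad_after = 3) {
  if (pad_before < 0 || pad_after < 0) abort("Paddings must be non-negative.")
  tt <- timeline$time
  mask <- rep(FALSE, length(tt))
  spans <- tibble::tibble(start = numeric(), end = numeric(), grab_id = integer())
  if (NROW(grabs) > 0) {
    spans <- tibble::tibble(
      start = grabs$time - pad_before,
      end = grabs$time +
        (if ("duration" %in% names(grabs)) grabs$duration else 0) + pad_after,
      grab_id = seq_len(nrow(grabs))
    ) |> dplyr::arrange(.data$start)
    # merge overlaps
    merged <- spans[1, ]
    if (nrow(spans) > 1) {
      for (i in 2:nrow(spans)) {
        last <- nrow(merged)
        if (spans$start[i] <= merged$end[last]) {
          merged$end[last] <- max(merged$end[last], spans$end[i])
        } else {
          merged <- dplyr::bind_rows(merged, spans[i, ])
        }
      }
    }
    spans <- merged
    for (i in seq_len(nrow(spans))) {
      mask <- mask | (tt >= spans$start[i] & tt <= spans$end[i])
    }
  }
  structure(list(mask = mask, spans = spans, time = tt), class = "artifact_mask")
}

#' Fraction of a window covered by an artifact mask
#'
#' @param mask an `artifact_mask`.
#' @param start,end window bounds in seconds.
#' @return fraction in \[0, 1\].
#' @export
masked_fraction <- function(mask, start, end) {
  sel <- mask$time >= start & mask$time < end
  if (!any(sel)) return(0)
  mean(mask$mask[sel])
}

#' Spectral overlap between a motion channel and skin conductance
#'
#' Cosine similarity of the normalized Fourier amplitude spectra of the two
#' signals over 0-2 Hz, quantifying how much gesture-band energy the
#' conductance trace shares with finger motion. Both spectra are
#' interpolated onto a common frequency grid, so the channels may differ in
#' sampling rate.
#'
#' @param flexion,edr signal tables (or tibbles with `time` and one value
#'   column) with a common duration of at least 10 s.
#' @param f_max upper frequency bound in Hz.
#' @return overlap score in \[0, 1\].
#' @export
spectral_overlap <- function(flexion, edr, f_max = 2) {
  amp_spec <- function(x) {
    fs <- signal_fs(x)
    v <- x$value - mean(x$value)
    n <- length(v)
    a <- abs(fft(v))[seq_len(n %/% 2 + 1)]
    tibble::tibble(freq = (seq_len(n %/% 2 + 1) - 1) * fs / n, amp = a)
  }
  dur <- min(diff(range(flexion$time)), diff(range(edr$time)))
  if (dur < 10) abort("Need at least 10 s of common signal.")
  grid <- seq(0.01, f_max, by = 0.01)
  s1 <- amp_spec(flexion)
  s2 <- amp_spec(edr)
  a1 <- approx(s1$freq, s1$amp, xout = grid, rule = 2)$y
  a2 <- approx(s2$freq, s2$amp, xout = grid, rule = 2)$y
  n1 <- sqrt(sum(a1^2))
  n2 <- sqrt(sum(a2^2))
  if (n1 == 0 || n2 == 0) {
    warn("Degenerate (zero) spectrum; overlap set to 0.")
    return(0)
  }
  sum(a1 * a2) / (n1 * n2)
}

#' Homogeneity of movement activity across stimulus classes
#'
#' Levene tests (mean-centered) of the activity indexes across arousal
#' classes, either within each subject or pooled between subjects. A
#' significant result flags movement heterogeneity that could confound
#' class-linked physiological differences.
#'
#' @param indexes tibble with an index column (`MAI` or `MRI`, or any named
#'   by `value_col`), a `class` column, and a `subject` column for the
#'   within-subject scope.
#' @param value_col name of the index column to test.
#' @param scope `"between_subject"` pools all rows into one test;
#'   `"within_subject"` runs one test per subject.
#' @param alpha significance level for the heterogeneity flag.
#' @return tibble: one row per test with `scope`, `subject`, `statistic`,
#'   `df1`, `df2`, `p_value`, `heterogeneous`.
#' @export
movement_homogeneity <- function(indexes, value_col = "MAI",
                                 scope = c("between_subject", "within_subject"),
                                 alpha = 0.05) {
  scope <- match.arg(scope)
  run_one <- function(df, subj) {
    if (dplyr::n_distinct(df$class) < 2 || any(table(df$class) < 2)) {
      abort("Each class needs at least 2 observations in every group.")
    }
    lt <- car::leveneTest(df[[value_col]], factor(df$class), center = mean)
    p <- lt[["Pr(>F)"]][1]
    stat <- lt[["F value"]][1]
    if (is.nan(stat)) { stat <- 0; p <- 1 }   # identical groups: no dispersion contrast
    tibble::tibble(
      scope = scope, subject = subj, statistic = stat,
      df1 = lt$Df[1], df2 = lt$Df[2], p_value = p,
      heterogeneous = is.finite(p) && p < alpha
    )
  }
  if (scope == "between_subject") {
    run_one(indexes, NA_integer_)
  } else {
    indexes |>
      dplyr::group_by(.data$subject) |>
      dplyr::group_map(~ run_one(.x, .y$subject)) |>
      dplyr::bind_rows()
  }
}
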