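#' Build the per-trial table for the conditioning study
#'
#' For every subject of a simulated (or imported) study-2 dataset: grabs are
#' detected from the flexion channels, the skin-conductance trace is
#' filtered and decomposed, and each trial row collects the grab latency
#' (first detected grab after the CS onset), the first-interval phasic
#' features (SCR onsets in `[CS onset + 1 s, CS onset + 4 s]`; the 1 s
#' latency gate is the cued-response convention), the HRV battery over the
#' 30 s window covering the outcome image and the following black screen,
#' and the first-interval amplitude sum normalized by the subject's own
#' maximum.
#'
#' @param dataset a `study2_dataset` from [simulate_study2()].
#' @param sc_min_latency latency gate after CS onset (seconds).
#' @param sc_window_end end of the first-interval window after CS onset.
#' @param hrv_window HRV window length from the outcome onset (seconds).
#' @return tibble with one row per trial: `subject`, `session`, `cs_type`,
#'   `trial`, `block`, `latency`, phasic features, `normalized_ampsum`, HRV
#'   features.
#' @export
build_trial_table <- function(dataset, sc_min_latency = 1, sc_window_end = 4,
                              hrv_window = 30) {
  stopifnot(inherits(dataset, "study2_dataset"))
  purrr::map_dfr(dataset$subjects, function(su) {
    cs <- su$events |> dplyr::filter(.data$type == "cs_onset")
    us <- su$events |> dplyr::filter(.data$type == "us_onset")
    grabs <- detect_grabs(su$flexion)
    mask <- build_artifact_mask(grabs, su$edr)
    dec <- deconvolve_edr(lowpass_zero_phase(su$edr))
    peaks <- detect_qrs_pan_tompkins(su$ecg)
    rr <- rr_from_peaks(peaks)
    end_t <- tail(su$ecg$time, 1)

    rows <- purrr::map_dfr(seq_len(nrow(cs)), function(i) {
      t0 <- cs$time[i]
      g <- grabs$time[grabs$time > t0]
      lat <- if (length(g)) g[1] - t0 else NA_real_
      ph <- phasic_features(dec, t0, window_len = sc_window_end,
                            min_latency = sc_min_latency, mask = mask)
      u0 <- us$time[us$session == cs$session[i] & us$cs_type == cs$cs_type[i] &
                      us$trial == cs$trial[i]][1]
      hrv <- if (is.finite(u0) && u0 + hrv_window <= end_t + 1e-9) {
        tryCatch(
          hrv_window_features(rr, tibble::tibble(start = u0, end = u0 + hrv_window)) |>
            dplyr::select(-"window_start", -"window_end"),
          error = function(e) empty_hrv_row()
        )
      } else empty_hrv_row()
      dplyr::bind_cols(
        tibble::tibble(
          subject = su$subject, session = cs$session[i], cs_type = cs$cs_type[i],
          trial = cs$trial[i],
          block = cut(cs$trial[i], c(0, 3, 6, 9),
                      labels = c("early", "middle", "late")),
          latency = lat
        ),
        ph, hrv
      )
    })
    max_amp <- max(rows$AmpSum, na.rm = TRUE)
    rows$normalized_ampsum <- if (is.finite(max_amp) && max_amp > 0) {
      rows$AmpSum / max_amp
    } else 0
    rows
  })
}

#' Block summaries of conditioned responses
#'
#' Aggregates the nine trials per CS type and session into early (1-3),
#' middle (4-6) and late (7-9) blocks.
#'
#' @param trials a trial table ([build_trial_table()]).
#' @return tibble: per subject, session, cs_type, block: mean and SD of
#'   `normalized_ampsum` and `latency`.
#' @export
block_summary <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject, .data$session, .data$cs_type, .data$block) |>
    dplyr::summarise(
      ampsum_mean = mean(.data$normalized_ampsum, na.rm = TRUE),
      ampsum_sd = sd(.data$normalized_ampsum, na.rm = TRUE),
      latency_mean = mean(.data$latency, na.rm = TRUE),
      latency_sd = sd(.data$latency, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Grab-latency conditioning statistics
#'
#' Paired Wilcoxon signed-rank comparisons of per-subject mean grab
#' latencies: reinforced vs non-reinforced trials within each session, and
#' reinforced trials across sessions. (The design is paired within
#' subjects, so the signed-rank test is the appropriate rank test.)
#'
#' @param trials a trial table.
#' @param alpha significance level.
#' @return tibble with one row per comparison: `comparison`, `n`,
#'   `statistic`, `p_value`, `significant`, `mean_1`, `mean_2`,
#'   `underpowered` flag (TRUE below 5 subjects).
#' @export
latency_stats <- function(trials, alpha = 0.05) {
  means <- trials |>
    dplyr::group_by(.data$subject, .data$session, .data$cs_type) |>
    dplyr::summarise(latency = mean(.data$latency, na.rm = TRUE), .groups = "drop")
  n_sub <- dplyr::n_distinct(means$subject)
  if (n_sub < 2) abort("Paired latency tests need at least 2 subjects.")
  pick <- function(session, cs) {
    means |>
      dplyr::filter(.data$session == !!session, .data$cs_type == !!cs) |>
      dplyr::arrange(.data$subject)
  }
  cmp <- function(label, a, b) {
    j <- dplyr::inner_join(a, b, by = "subject", suffix = c("_1", "_2"))
    j <- j[is.finite(j$latency_1) & is.finite(j$latency_2), ]
    if (nrow(j) < 2) {
      return(tibble::tibble(
        comparison = label, n = nrow(j), statistic = NA_real_,
        p_value = NA_real_, significant = FALSE,
        mean_1 = if (nrow(j)) mean(j$latency_1) else NA_real_,
        mean_2 = if (nrow(j)) mean(j$latency_2) else NA_real_,
        underpowered = TRUE
      ))
    }
    w <- suppressWarnings(
      wilcox.test(j$latency_1, j$latency_2, paired = TRUE)
    )
    tibble::tibble(
      comparison = label, n = nrow(j), statistic = unname(w$statistic),
      p_value = w$p.value, significant = is.finite(w$p.value) & w$p.value < alpha,
      mean_1 = mean(j$latency_1), mean_2 = mean(j$latency_2),
      underpowered = nrow(j) < 5
    )
  }
  dplyr::bind_rows(
    cmp("acquisition: CS+ vs CS-",
        pick("acquisition", "CS+"), pick("acquisition", "CS-")),
    cmp("extinction: CS+ vs CS-",
        pick("extinction", "CS+"), pick("extinction", "CS-")),
    cmp("CS+: acquisition vs extinction",
        pick("acquisition", "CS+"), pick("extinction", "CS+"))
  )
}

#' First-interval SCR block statistics
#'
#' Rank-based comparisons of normalized first-interval amplitude sums
#' between trial blocks, per CS type and session: a Kruskal-Wallis omnibus
#' across the three blocks (on per-subject block means) followed by paired
#' Wilcoxon block contrasts, Bonferroni-corrected. Also returns the
#' trial-by-trial group means with dispersion for plotting.
#'
#' @param trials a trial table.
#' @param alpha significance level (applied after correction).
#' @return list: `omnibus` (per session x cs_type), `pairwise`
#'   (block contrasts), `trialwise` (per trial mean +/- sem).
#' @export
edr_block_stats <- function(trials, alpha = 0.05) {
  bs <- block_summary(trials)
  omnibus <- bs |>
    dplyr::group_by(.data$session, .data$cs_type) |>
    dplyr::group_map(~ {
      if (dplyr::n_distinct(.x$block) < 2) return(NULL)
      kw <- kruskal.test(.x$ampsum_mean, factor(.x$block))
      tibble::tibble(session = .y$session, cs_type = .y$cs_type,
                     statistic = unname(kw$statistic), df = unname(kw$parameter),
                     p_value = kw$p.value)
    }) |> dplyr::bind_rows()
  prs <- list(c("early", "middle"), c("middle", "late"), c("early", "late"))
  pairwise <- bs |>
    dplyr::group_by(.data$session, .data$cs_type) |>
    dplyr::group_map(~ {
      purrr::map_dfr(prs, function(p) {
        a <- .x[.x$block == p[1], c("subject", "ampsum_mean")]
        b <- .x[.x$block == p[2], c("subject", "ampsum_mean")]
        j <- dplyr::inner_join(a, b, by = "subject", suffix = c("_1", "_2"))
        if (nrow(j) < 2) return(NULL)
        w <- suppressWarnings(
          wilcox.test(j$ampsum_mean_1, j$ampsum_mean_2, paired = TRUE)
        )
        tibble::tibble(session = .y$session, cs_type = .y$cs_type,
                       block1 = p[1], block2 = p[2], n = nrow(j),
                       p_value = w$p.value)
      })
    }) |> dplyr::bind_rows()
  if (nrow(pairwise)) {
    pairwise <- pairwise |>
      dplyr::group_by(.data$session, .data$cs_type) |>
      dplyr::mutate(p_adjusted = pmin(1, .data$p_value * dplyr::n()),
                    significant = .data$p_adjusted < alpha) |>
      dplyr::ungroup()
  }
  trialwise <- trials |>
    dplyr::group_by(.data$session, .data$cs_type, .data$trial) |>
    dplyr::summarise(
      mean = mean(.data$normalized_ampsum, na.rm = TRUE),
      sem = sd(.data$normalized_ampsum, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$normalized_ampsum))),
      .groups = "drop"
    )
  list(omnibus = omnibus, pairwise = pairwise, trialwise = trialwise)
}

#' HRV conditioning statistics
#'
#' Per HRV feature: a Friedman test across the four per-subject condition
#' means (CS+/CS- by acquisition/extinction), paired Wilcoxon CS+ vs CS-
#' within each session, and the vagal-trend analysis over the first four
#' extinction CS+ trials (per-subject ranks; first vs fourth paired
#' Wilcoxon) for the features indexing parasympathetic control (RMSSD, HF,
#' SD1 by default). Subjects with incomplete coverage are dropped from the
#' affected test; constant features are skipped.
#'
#' @param trials a trial table with HRV feature columns.
#' @param features feature columns to test.
#' @param trend_features features entered in the extinction trend analysis.
#' @param alpha significance level.
#' @return list: `friedman`, `wilcoxon`, `trend` tibbles.
#' @export
hrv_conditioning_stats <- function(trials,
                                   features = c("MNN", "median_nn", "RRmean",
                                                "RMSSD", "HF", "SD1",
                                                "triangular_index"),
                                   trend_features = c("RMSSD", "HF", "SD1"),
                                   alpha = 0.05) {
  features <- intersect(features, names(trials))
  cond_means <- trials |>
    dplyr::group_by(.data$subject, .data$session, .data$cs_type) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(features),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  friedman <- purrr::map_dfr(features, function(f) {
    wide <- cond_means |>
      dplyr::select("subject", "session", "cs_type", value = dplyr::all_of(f)) |>
      tidyr::pivot_wider(names_from = c("session", "cs_type"),
                         values_from = "value")
    m <- as.matrix(wide[, -1])
    ok <- stats::complete.cases(m) & apply(m, 1, function(r) all(is.finite(r)))
    m <- m[ok, , drop = FALSE]
    if (nrow(m) < 3 || ncol(m) != 4) {
      return(tibble::tibble(feature = f, n = nrow(m), statistic = NA_real_,
                            p_value = NA_real_, significant = FALSE,
                            skipped = TRUE, reason = "insufficient complete subjects"))
    }
    if (any(apply(m, 2, function(v) length(unique(v)) == 1)) &&
        length(unique(as.vector(m))) == 1) {
      return(tibble::tibble(feature = f, n = nrow(m), statistic = NA_real_,
                            p_value = NA_real_, significant = FALSE,
                            skipped = TRUE, reason = "constant feature"))
    }
    fr <- friedman.test(m)
    tibble::tibble(feature = f, n = nrow(m), statistic = unname(fr$statistic),
                   p_value = fr$p.value,
                   significant = is.finite(fr$p.value) & fr$p.value < alpha,
                   skipped = FALSE, reason = NA_character_)
  })
  wilcoxon <- purrr::map_dfr(features, function(f) {
    purrr::map_dfr(c("acquisition", "extinction"), function(sess) {
      a <- cond_means[cond_means$session == sess & cond_means$cs_type == "CS+",
                      c("subject", f)]
      b <- cond_means[cond_means$session == sess & cond_means$cs_type == "CS-",
                      c("subject", f)]
      j <- dplyr::inner_join(a, b, by = "subject", suffix = c("_p", "_m"))
      v1 <- j[[paste0(f, "_p")]]
      v2 <- j[[paste0(f, "_m")]]
      ok <- is.finite(v1) & is.finite(v2)
      if (sum(ok) < 3 || all(v1[ok] == v2[ok])) {
        return(tibble::tibble(feature = f, session = sess, n = sum(ok),
                              p_value = NA_real_, significant = FALSE))
      }
      w <- suppressWarnings(wilcox.test(v1[ok], v2[ok], paired = TRUE))
      tibble::tibble(feature = f, session = sess, n = sum(ok),
                     p_value = w$p.value,
                     significant = is.finite(w$p.value) & w$p.value < alpha)
    })
  })
  # extinction trend: first four CS+ trials
  ext4 <- trials |>
    dplyr::filter(.data$session == "extinction", .data$cs_type == "CS+",
                  .data$trial <= 4)
  trend <- purrr::map_dfr(intersect(trend_features, names(trials)), function(f) {
    wide <- ext4 |>
      dplyr::select("subject", "trial", value = dplyr::all_of(f)) |>
      tidyr::pivot_wider(names_from = "trial", values_from = "value")
    m <- as.matrix(wide[, -1])
    ok <- apply(m, 1, function(r) all(is.finite(r)))
    m <- m[ok, , drop = FALSE]
    if (nrow(m) < 3 || ncol(m) < 4) {
      return(tibble::tibble(feature = f, n = nrow(m), mean_rank_slope = NA_real_,
                            p_first_vs_fourth = NA_real_, significant = FALSE))
    }
    ranks <- t(apply(m, 1, rank))
    slope <- mean(apply(ranks, 1, function(r) stats::coef(stats::lm(r ~ seq_along(r)))[2]))
    diffs <- m[, 1] - m[, 4]
    # directional test: the hypothesis is a decline, first > fourth
    w <- if (all(diffs == 0)) list(p.value = NA_real_) else {
      suppressWarnings(wilcox.test(m[, 1], m[, 4], paired = TRUE,
                                   alternative = "greater"))
    }
    tibble::tibble(feature = f, n = nrow(m), mean_rank_slope = slope,
                   p_first_vs_fourth = w$p.value,
                   significant = is.finite(w$p.value) & w$p.value < alpha)
  })
  list(friedman = friedman, wilcoxon = wilcoxon, trend = trend)
}

#' Self-assessment questionnaire statistics
#'
#' Paired comparison of arousal ratings for the reinforced vs non-reinforced
#' stimulus: a Lilliefors-corrected normality screen on the paired
#' differences routes to a paired t-test or a Wilcoxon signed-rank fallback.
#' Awareness ratings (Likert -5..5) are summarized as their mean and the
#' fraction at or above the agreement cutoff.
#'
#' @param ratings tibble: `subject`, `cs_type` (`CS+`/`CS-`), `arousal`.
#' @param awareness numeric vector of Likert awareness ratings (optional).
#' @param agreement_cutoff cutoff defining "agreement".
#' @param alpha significance level.
#' @return list: `arousal_test` (one-row tibble), `awareness` (one-row
#'   tibble or NULL).
#' @export
questionnaire_stats <- function(ratings, awareness = NULL,
                                agreement_cutoff = 3, alpha = 0.05) {
  wide <- ratings |>
    dplyr::select("subject", "cs_type", "arousal") |>
    tidyr::pivot_wider(names_from = "cs_type", values_from = "arousal")
  if (!all(c("CS+", "CS-") %in% names(wide)) || anyNA(wide[c("CS+", "CS-")])) {
    abort("Ratings must be paired: one CS+ and one CS- rating per subject.")
  }
  d <- wide[["CS+"]] - wide[["CS-"]]
  normal <- length(unique(d)) >= 4 && length(d) >= 5 &&
    nortest::lillie.test(d)$p.value > alpha
  if (all(d == 0)) {
    test <- tibble::tibble(test = "degenerate", n = length(d),
                           statistic = 0, p_value = 1, significant = FALSE,
                           mean_cs_plus = mean(wide[["CS+"]]),
                           mean_cs_minus = mean(wide[["CS-"]]))
  } else if (normal) {
    tt <- t.test(wide[["CS+"]], wide[["CS-"]], paired = TRUE)
    test <- tibble::tibble(test = "paired_t", n = length(d),
                           statistic = unname(tt$statistic), p_value = tt$p.value,
                           significant = tt$p.value < alpha,
                           mean_cs_plus = mean(wide[["CS+"]]),
                           mean_cs_minus = mean(wide[["CS-"]]))
  } else {
    w <- suppressWarnings(wilcox.test(wide[["CS+"]], wide[["CS-"]], paired = TRUE))
    test <- tibble::tibble(test = "signed_rank", n = length(d),
                           statistic = unname(w$statistic), p_value = w$p.value,
                           significant = is.finite(w$p.value) & w$p.value < alpha,
                           mean_cs_plus = mean(wide[["CS+"]]),
                           mean_cs_minus = mean(wide[["CS-"]]))
  }
  aw <- if (!is.null(awareness)) {
    tibble::tibble(mean_rating = mean(awareness),
                   agreement_fraction = mean(awareness >= agreement_cutoff))
  }
  list(arousal_test = test, awareness = aw)
}
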