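#' Simulate the picture-viewing study
#'
#' Generates, for each synthetic subject, the full channel set (ECG, skin
#' conductance, tri-axial acceleration and orientation, five finger-flexion
#' channels), the protocol event table (5-min baseline, then the 12 pictures
#' in randomized order, 20 s each with 20 s black screens and a grab gesture
#' before each trial), and a ground-truth sidecar (beat times, sudomotor
#' impulses, grab times) for recovery testing. Stimulus-locked sudomotor
#' impulse area grows with picture arousal and RR intervals shorten with
#' arousal according to the effect model.
#'
#' @param n_subjects number of subjects (>= 1); the study recorded 7.
#' @param protocol a [study1_protocol()].
#' @param effects an [effect_model()].
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return object of class `study1_dataset`: list with `subjects` (list of
#'   per-subject recordings), `protocol`, `effects`.
#' @export
simulate_study1 <- function(n_subjects = 7, protocol = study1_protocol(),
                            effects = effect_model(), seed = NULL) {
  if (!identical(protocol$study, "study1")) abort("`protocol` must be a study-1 protocol.")
  if (!is.numeric(n_subjects) || n_subjects < 1) abort("`n_subjects` must be >= 1.")
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sim_study1_subject(s, protocol, effects,
                       seed = if (is.null(seed)) NULL else (seed * 1000L + s) %% 2147483647L)
  })
  structure(list(subjects = subjects, protocol = protocol, effects = effects),
            class = "study1_dataset")
}

sim_study1_subject <- function(subject, protocol, effects, seed = NULL) {
  with_seed(seed, {
    cat12 <- protocol$catalog[sample.int(nrow(protocol$catalog)), ]
    trial_len <- protocol$stimulus_duration + protocol$black_duration
    onsets <- protocol$baseline_duration + 2 + (seq_len(nrow(cat12)) - 1) * trial_len
    grabs <- onsets - 2
    duration <- max(onsets) + trial_len

    events <- dplyr::bind_rows(
      tibble::tibble(
        time = onsets, type = "stimulus_onset",
        stimulus_id = cat12$id, arousal = cat12$arousal_mean
      ),
      tibble::tibble(time = grabs, type = "grab",
                     stimulus_id = cat12$id, arousal = NA_real_)
    ) |> dplyr::arrange(.data$time)

    # --- sudomotor ground truth -------------------------------------------
    amps <- pmax(
      0.01,
      effects$sc_base_amp +
        effects$sc_arousal_gain * (cat12$arousal_mean - 4.5) +
        rnorm(nrow(cat12), 0, effects$sc_amp_noise)
    )
    t_imp <- onsets + runif(nrow(cat12), 1.3, 3.2)
    second <- runif(nrow(cat12)) <
      pmin(1, pmax(0, 0.3 + 2 * effects$sc_arousal_gain * (cat12$arousal_mean - 4.5)))
    imp <- tibble::tibble(time = t_imp, amplitude = amps, nonspecific = FALSE)
    if (any(second)) {
      imp <- dplyr::bind_rows(imp, tibble::tibble(
        time = onsets[second] + runif(sum(second), 3.6, 4.8),
        amplitude = 0.6 * amps[second], nonspecific = FALSE
      ))
    }
    n_ns <- rpois(1, effects$nonspecific_rate * duration)
    if (n_ns > 0) {
      imp <- dplyr::bind_rows(imp, tibble::tibble(
        time = runif(n_ns, 5, duration - 10),
        amplitude = effects$nonspecific_amp * runif(n_ns, 0.5, 1.5),
        nonspecific = TRUE
      ))
    }
    knots <- seq(0, duration, by = 60)
    tonic <- tibble::tibble(
      time = knots,
      level = pmin(6, pmax(0.5, 2 + cumsum(rnorm(length(knots), 0, 0.15))))
    )
    sudo <- sudomotor_truth(imp, tonic, duration)
    edr <- synthesize_edr(sudo, fs = 100, noise_sd = effects$edr_noise_sd)

    # --- motion + grab artifact -------------------------------------------
    n_walk <- sample(1:3, 1)
    walk <- tibble::tibble(
      start = runif(n_walk, protocol$baseline_duration, duration - 30),
      end = NA_real_
    )
    walk$end <- walk$start + runif(n_walk, 5, 15)
    motion <- synthesize_motion(
      duration, grab_times = grabs, walk_segments = walk, fs = 100,
      artifact_amp = effects$artifact_amp, noise_sd = effects$motion_noise_sd
    )
    n_edr <- min(nrow(edr), nrow(motion$edr_artifact))
    edr$value[seq_len(n_edr)] <- edr$value[seq_len(n_edr)] +
      motion$edr_artifact$value[seq_len(n_edr)]

    # --- ECG ---------------------------------------------------------------
    hr0 <- 72 + rnorm(1, 0, 3)
    arousal_at <- stimulus_lookup(onsets, protocol$stimulus_duration, cat12$arousal_mean)
    rr_fn <- function(t) {
      60 / hr0 +
        0.02 * sin(2 * pi * 0.1 * t) + 0.025 * sin(2 * pi * 0.25 * t) -
        effects$hr_arousal_gain * (arousal_at(t) - 4.5)
    }
    beats <- gen_beat_times(duration, rr_fn, noise_sd = 0.01)
    ecg <- synthesize_ecg(list(beat_times = beats), fs = 250,
                          noise_sd = effects$ecg_noise_sd, duration = duration)

    list(
      subject = subject, ecg = ecg, edr = edr,
      accel = motion$accel, orient = motion$orient, flexion = motion$flexion,
      events = events,
      truth = list(beat_times = beats, sudomotor = sudo, grab_times = grabs,
                   stimulus_order = cat12$id)
    )
  })
}

# stepwise lookup: value inside [onset, onset+len) windows, 4.5 elsewhere
stimulus_lookup <- function(onsets, len, values, neutral = 4.5) {
  force(onsets); force(len); force(values)
  function(t) {
    i <- findInterval(t, onsets)
    if (i >= 1 && t < onsets[i] + len) values[i] else neutral
  }
}

#' Simulate the classical-conditioning study
#'
#' Generates per-subject recordings for an acquisition session (9 CS+ and 9
#' CS- trials intermixed at random) and an extinction session (same layout,
#' neutral outcomes only). The conditioned first-interval sudomotor response
#' to CS+ follows a saturating learning curve over acquisition trials and
#' decays during extinction; CS+ grab latencies carry the configured
#' increment during acquisition; RR intervals lengthen on reinforced trials
#' during acquisition (flipped in extinction) and the respiratory-band RR
#' modulation declines across extinction CS+ trials (the vagal-withdrawal
#' analogue).
#'
#' @param n_subjects number of subjects (>= 1); the study recorded 11.
#' @param protocol a [study2_protocol()].
#' @param effects an [effect_model()].
#' @param seed integer master seed.
#' @return object of class `study2_dataset`.
#' @export
simulate_study2 <- function(n_subjects = 11, protocol = study2_protocol(),
                            effects = effect_model(), seed = NULL) {
  if (!identical(protocol$study, "study2")) abort("`protocol` must be a study-2 protocol.")
  if (!is.numeric(n_subjects) || n_subjects < 1) abort("`n_subjects` must be >= 1.")
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sim_study2_subject(s, protocol, effects,
                       seed = if (is.null(seed)) NULL else (seed * 1000L + 500L + s) %% 2147483647L)
  })
  structure(list(subjects = subjects, protocol = protocol, effects = effects),
            class = "study2_dataset")
}

sim_study2_subject <- function(subject, protocol, effects, seed = NULL) {
  with_seed(seed, {
    lat_offset <- rnorm(1, 0, effects$latency_subject_sd)
    t_cursor <- protocol$baseline_duration
    trials <- list()
    imps <- list()
    hf_windows <- list()   # (start, end, hf_scale, rr_shift)
    for (session in c("acquisition", "extinction")) {
      cs_seq <- sample(rep(c("CS+", "CS-"), protocol$n_per_cs))
      idx_ct <- c("CS+" = 0L, "CS-" = 0L)
      for (cs in cs_seq) {
        idx_ct[cs] <- idx_ct[cs] + 1L
        j <- idx_ct[cs]
        cs_onset <- t_cursor
        lat <- effects$latency_base + lat_offset +
          (cs == "CS+" && session == "acquisition") * effects$latency_increment +
          rnorm(1, 0, effects$latency_trial_sd)
        lat <- max(lat, 1.2)
        grab <- cs_onset + lat
        us_onset <- grab
        us_type <- if (session == "acquisition" && cs == "CS+") "US+" else "US-"
        us_arousal <- if (us_type == "US+") protocol$us_plus_arousal else protocol$us_minus_arousal

        # conditioned first-interval response
        cr_amp <- effects$cs_minus_amp +
          if (cs == "CS+") {
            if (session == "acquisition") {
              effects$learning_asymptote * (1 - exp(-effects$learning_rate * j))
            } else {
              effects$learning_asymptote * exp(-effects$extinction_decay * j)
            }
          } else 0
        cr_amp <- max(0.005, cr_amp + rnorm(1, 0, effects$sc_amp_noise))
        imps[[length(imps) + 1L]] <- tibble::tibble(
          time = cs_onset + runif(1, 1.6, 2.3), amplitude = cr_amp, nonspecific = FALSE
        )
        # unconditioned response, arousal-scaled
        us_amp <- max(0.01, effects$sc_base_amp +
                        effects$sc_arousal_gain * (us_arousal - 4.5) +
                        rnorm(1, 0, effects$sc_amp_noise))
        imps[[length(imps) + 1L]] <- tibble::tibble(
          time = us_onset + runif(1, 1.5, 3), amplitude = us_amp, nonspecific = FALSE
        )

        # HRV effect window: US + black screen
        rr_shift <- effects$rr_cs_gain / 2 *
          (if (cs == "CS+") 1 else -1) * (if (session == "acquisition") 1 else -1)
        hf_scale <- 1
        if (session == "extinction" && cs == "CS+") {
          hf_scale <- max(0.2, 1 - effects$hf_extinction_decline / max(effects$hf_amp, 1e-9) * (j - 1))
        }
        black <- runif(1, protocol$post_us_range[1], protocol$post_us_range[2])
        hf_windows[[length(hf_windows) + 1L]] <- tibble::tibble(
          start = us_onset, end = us_onset + protocol$us_duration + black,
          hf_scale = hf_scale, rr_shift = rr_shift
        )
        trials[[length(trials) + 1L]] <- tibble::tibble(
          session = session, cs_type = cs, trial = as.integer(j),
          cs_onset = cs_onset, grab_time = grab, latency = lat,
          us_onset = us_onset, us_type = us_type,
          true_cr_amp = cr_amp
        )
        t_cursor <- us_onset + protocol$us_duration + black
      }
      if (session == "acquisition") t_cursor <- t_cursor + protocol$rest_duration
    }
    trials <- dplyr::bind_rows(trials)
    windows <- dplyr::bind_rows(hf_windows)
    duration <- t_cursor + 10

    imp <- dplyr::bind_rows(imps)
    n_ns <- rpois(1, effects$nonspecific_rate * duration)
    if (n_ns > 0) {
      imp <- dplyr::bind_rows(imp, tibble::tibble(
        time = runif(n_ns, 5, duration - 10),
        amplitude = effects$nonspecific_amp * runif(n_ns, 0.5, 1.5),
        nonspecific = TRUE
      ))
    }
    knots <- seq(0, duration, by = 60)
    tonic <- tibble::tibble(
      time = knots,
      level = pmin(6, pmax(0.5, 2 + cumsum(rnorm(length(knots), 0, 0.15))))
    )
    sudo <- sudomotor_truth(imp, tonic, duration)
    edr <- synthesize_edr(sudo, fs = 100, noise_sd = effects$edr_noise_sd)

    motion <- synthesize_motion(
      duration, grab_times = trials$grab_time, fs = 100,
      artifact_amp = effects$artifact_amp, noise_sd = effects$motion_noise_sd
    )
    n_edr <- min(nrow(edr), nrow(motion$edr_artifact))
    edr$value[seq_len(n_edr)] <- edr$value[seq_len(n_edr)] +
      motion$edr_artifact$value[seq_len(n_edr)]

    hr0 <- 72 + rnorm(1, 0, 3)
    win_fn <- function(t) {
      i <- findInterval(t, windows$start)
      if (i >= 1 && t < windows$end[i]) {
        c(windows$rr_shift[i], windows$hf_scale[i])
      } else c(0, 1)
    }
    rr_fn <- function(t) {
      w <- win_fn(t)
      60 / hr0 + w[1] +
        0.02 * sin(2 * pi * 0.1 * t) +
        effects$hf_amp * w[2] * sin(2 * pi * 0.25 * t)
    }
    beats <- gen_beat_times(duration, rr_fn, noise_sd = 0.01)
    ecg <- synthesize_ecg(list(beat_times = beats), fs = 250,
                          noise_sd = effects$ecg_noise_sd, duration = duration)

    events <- dplyr::bind_rows(
      trials |>
        dplyr::transmute(time = .data$cs_onset, type = "cs_onset",
                         session = .data$session, cs_type = .data$cs_type,
                         trial = .data$trial, us_type = .data$us_type),
      trials |>
        dplyr::transmute(time = .data$grab_time, type = "grab",
                         session = .data$session, cs_type = .data$cs_type,
                         trial = .data$trial, us_type = .data$us_type),
      trials |>
        dplyr::transmute(time = .data$us_onset, type = "us_onset",
                         session = .data$session, cs_type = .data$cs_type,
                         trial = .data$trial, us_type = .data$us_type)
    ) |> dplyr::arrange(.data$time)

    list(
      subject = subject, ecg = ecg, edr = edr,
      accel = motion$accel, orient = motion$orient, flexion = motion$flexion,
      events = events,
      truth = list(beat_times = beats, sudomotor = sudo,
                   grab_times = trials$grab_time, trials = trials)
    )
  })
}
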