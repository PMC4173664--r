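#' The 12-picture arousal stimulus catalog
#'
#' The normed picture set used by the picture-viewing study: 12 IAPS images
#' spanning the arousal scale from 1.72 to 7.34, with the published class
#' memberships for the three analysis subsets. Subset labels are taken from
#' the catalog columns as printed (membership is not recomputed from the
#' arousal ranges; two borderline pictures at 3.18 and 3.72 are listed as
#' low-arousal in subset alpha even though the range description says 1-3).
#'
#' @return tibble with one row per stimulus: `id`, `iaps_id`, `description`,
#'   `arousal_mean`, `arousal_sd`, `subset_alpha`, `subset_beta`,
#'   `subset_gamma` (class labels `A1`/`A2`/`A3`, NA when the stimulus is not
#'   part of that subset).
#' @export
stimulus_catalog <- function() {
  tibble::tribble(
    ~id, ~iaps_id, ~description, ~arousal_mean, ~arousal_sd, ~subset_alpha, ~subset_beta, ~subset_gamma,
    1L, "7175", "Lamp",        1.72, 1.26, "A1", "A1", "A1",
    2L, "7020", "Fan",         2.17, 1.71, "A1", "A1", "A1",
    3L, "5030", "Flower",      2.74, 2.13, "A1", "A1", "A1",
    4L, "7547", "Bridge",      3.18, 2.01, "A1", NA,   "A1",
    5L, "7512", "Chess",       3.72, 2.07, "A1", NA,   "A2",
    6L, "9280", "Smoke",       4.26, 2.44, NA,   NA,   "A2",
    7L, "9171", "Fisherman",   4.72, 2.17, NA,   NA,   "A2",
    8L, "9582", "Dental Exam", 5.29, 2.21, "A2", NA,   "A2",
    9L, "9611", "Plane Crash", 5.75, 2.44, "A2", NA,   "A3",
    10L, "9622", "Jet",        6.26, 1.98, "A2", "A2", "A3",
    11L, "9412", "Dead Man",   6.72, 2.07, "A2", "A2", "A3",
    12L, "3000", "Mutilation", 7.34, 2.27, "A2", "A2", "A3"
  )
}

#' Protocol constants for the picture-viewing study
#'
#' @param baseline_duration initial black-screen baseline in seconds
#'   (default 5 min).
#' @param stimulus_duration picture display time in seconds.
#' @param black_duration inter-stimulus black screen in seconds.
#' @param catalog stimulus catalog, default [stimulus_catalog()].
#' @return list of class `protocol_spec` with `study = "study1"`.
#' @export
study1_protocol <- function(baseline_duration = 300, stimulus_duration = 20,
                            black_duration = 20, catalog = stimulus_catalog()) {
  if (nrow(catalog) != 12) abort("The study-1 catalog must hold exactly 12 stimuli.")
  structure(
    list(
      study = "study1",
      baseline_duration = baseline_duration,
      stimulus_duration = stimulus_duration,
      black_duration = black_duration,
      catalog = catalog
    ),
    class = "protocol_spec"
  )
}

#' Protocol constants for the conditioning study
#'
#' Each session holds 9 reinforced (CS+) and 9 non-reinforced (CS-) trials in
#' random order. The unconditioned image is shown for 15 s and followed by a
#' black screen whose duration is uniform on `post_us_range` (the text's
#' 17 +/- 3 s).
#'
#' @param baseline_duration pre-session relaxation period in seconds.
#' @param rest_duration rest between acquisition and extinction in seconds.
#' @param n_per_cs trials per CS type per session.
#' @param us_duration unconditioned-stimulus display time in seconds.
#' @param post_us_range black-screen interval bounds in seconds.
#' @param us_plus_arousal,us_minus_arousal mean arousal of the reinforcing /
#'   neutral image sets.
#' @return list of class `protocol_spec` with `study = "study2"`.
#' @export
study2_protocol <- function(baseline_duration = 300, rest_duration = 300,
                            n_per_cs = 9, us_duration = 15,
                            post_us_range = c(14, 20),
                            us_plus_arousal = 6.95, us_minus_arousal = 2.42) {
  structure(
    list(
      study = "study2",
      baseline_duration = baseline_duration,
      rest_duration = rest_duration,
      n_per_cs = n_per_cs,
      us_duration = us_duration,
      post_us_range = post_us_range,
      us_plus_arousal = us_plus_arousal,
      us_minus_arousal = us_minus_arousal
    ),
    class = "protocol_spec"
  )
}

#' Effect model driving the synthetic studies
#'
#' Encodes the physiological effects the two studies test for, as tunable
#' gains; setting all gains to zero makes the class labels statistically
#' exchangeable, which is the null condition the calibration tests rely on.
#'
#' @param sc_arousal_gain driver impulse area per arousal unit (uS.s);
#'   stimulus-locked sudomotor bursts grow with picture arousal.
#' @param sc_base_amp baseline stimulus-locked impulse area (uS.s).
#' @param sc_amp_noise SD of the impulse-area noise (uS.s).
#' @param hr_arousal_gain RR shortening per arousal unit during a stimulus
#'   (seconds of RR per arousal unit).
#' @param learning_asymptote,learning_rate conditioned-response growth over
#'   acquisition trials: `amp = asymptote * (1 - exp(-rate * trial))`.
#' @param extinction_decay decay rate of the conditioned response during
#'   extinction: `amp = asymptote * exp(-decay * trial)`.
#' @param cs_minus_amp first-interval impulse area for non-reinforced trials.
#' @param latency_base mean grab latency in seconds.
#' @param latency_increment extra CS+ latency during acquisition (seconds).
#' @param latency_subject_sd,latency_trial_sd latency noise components.
#' @param rr_cs_gain RR lengthening on reinforced trials during acquisition
#'   (seconds), sign-flipped in extinction.
#' @param hf_amp,hf_extinction_decline respiratory-band RR modulation
#'   amplitude (s) and its per-trial decline over extinction CS+ trials
#'   (vagal-withdrawal analogue driving RMSSD/HF/SD1 downwards).
#' @param nonspecific_rate spontaneous SCR rate (per second).
#' @param nonspecific_amp spontaneous SCR impulse area (uS.s).
#' @param ecg_noise_sd,edr_noise_sd,motion_noise_sd channel noise floors.
#' @param artifact_amp grab artifact amplitude on the skin-conductance
#'   channel (uS).
#' @return list of class `effect_model`.
#' @export
effect_model <- function(sc_arousal_gain = 0.08,
                         sc_base_amp = 0.35,
                         sc_amp_noise = 0.04,
                         hr_arousal_gain = 0.004,
                         learning_asymptote = 0.5,
                         learning_rate = 0.6,
                         extinction_decay = 0.5,
                         cs_minus_amp = 0.08,
                         latency_base = 3.4,
                         latency_increment = 0.32,
                         latency_subject_sd = 0.2,
                         latency_trial_sd = 0.45,
                         rr_cs_gain = 0.02,
                         hf_amp = 0.03,
                         hf_extinction_decline = 0.006,
                         nonspecific_rate = 1 / 90,
                         nonspecific_amp = 0.12,
                         ecg_noise_sd = 0.02,
                         edr_noise_sd = 0.005,
                         motion_noise_sd = 0.02,
                         artifact_amp = 0.3) {
  out <- as.list(environment())
  if (!all(vapply(out, function(x) is.numeric(x) && all(is.finite(x)), logical(1)))) {
    abort("All effect-model gains must be finite numbers.")
  }
  structure(out, class = "effect_model")
}

#' Null effect model (all gains zero)
#'
#' Convenience wrapper: every class-linked gain is zero so arousal labels and
#' CS types are exchangeable; only noise remains.
#'
#' @param ... overrides forwarded to [effect_model()].
#' @export
null_effect_model <- function(...) {
  effect_model(
    sc_arousal_gain = 0, hr_arousal_gain = 0,
    learning_asymptote = 0, extinction_decay = 0,
    latency_increment = 0, rr_cs_gain = 0, hf_extinction_decline = 0,
    ...
  )
}
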