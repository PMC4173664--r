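short_study2 <- function(n_subjects = 2, seed = 77, effects = effect_model()) {
  simulate_study2(
    n_subjects = n_subjects,
    protocol = study2_protocol(baseline_duration = 30, rest_duration = 30),
    effects = effects, seed = seed
  )
}

test_that("trial table covers both sessions with recovered latencies", {
  ds <- short_study2(2)
  tt <- build_trial_table(ds)
  expect_equal(nrow(tt), 72)
  expect_true(all(table(tt$subject) == 36))
  # blocks partition the 9 trials per CS type
  expect_true(all(table(tt$block, tt$session, tt$cs_type) == 6))
  expect_true(all(tt$trial >= 1 & tt$trial <= 9))
  # latencies match the injected ground truth
  for (s in 1:2) {
    truth <- ds$subjects[[s]]$truth$trials
    sub <- tt[tt$subject == s, ]
    m <- dplyr::inner_join(
      truth[, c("session", "cs_type", "trial", "latency")],
      sub[, c("session", "cs_type", "trial", "latency")],
      by = c("session", "cs_type", "trial")
    )
    ok <- is.finite(m$latency.y)
    expect_gt(mean(ok), 0.95)
    expect_lt(max(abs(m$latency.x[ok] - m$latency.y[ok])), 0.1)
  }
  # normalization contract: per-subject max is exactly 1
  mx <- tapply(tt$normalized_ampsum, tt$subject, max)
  expect_true(all(abs(mx - 1) < 1e-12))
  expect_true(all(tt$normalized_ampsum >= 0 & tt$normalized_ampsum <= 1))
})

test_that("latency gate: no early-onset SCR enters first-interval features", {
  # impulse 0.4 s after CS onset must not contribute
  tr <- sudomotor_truth(data.frame(time = 30.4, amplitude = 0.5),
                        tonic = 2, duration = 70)
  dec <- deconvolve_edr(synthesize_edr(tr))
  ph <- phasic_features(dec, 30, window_len = 4, min_latency = 1)
  expect_equal(ph$nSCR, 0)
  expect_equal(ph$AmpSum, 0)
})

test_that("latency statistics detect the acquisition increment on clear data", {
  set.seed(1)
  mk_trials <- function(inc) {
    purrr::map_dfr(1:11, function(s) {
      base <- 3.4 + rnorm(1, 0, 0.2)
      tibble::tibble(
        subject = s,
        session = rep(c("acquisition", "extinction"), each = 2),
        cs_type = rep(c("CS+", "CS-"), 2),
        latency = base + c(inc, 0, 0, 0) + rnorm(4, 0, 0.1),
        normalized_ampsum = runif(4)
      )
    })
  }
  r <- latency_stats(mk_trials(0.6))
  expect_true(r$significant[r$comparison == "acquisition: CS+ vs CS-"])
  expect_false(r$underpowered[1])
  expect_error(latency_stats(mk_trials(0)[mk_trials(0)$subject == 1, ]),
               "2 subjects")
})

test_that("block statistics expose the learning-curve contrast", {
  ds <- short_study2(4, seed = 13)
  tt <- build_trial_table(ds)
  eb <- edr_block_stats(tt)
  expect_true(all(c("omnibus", "pairwise", "trialwise") %in% names(eb)))
  # every trial appears exactly once in the trialwise summary
  expect_equal(nrow(eb$trialwise), 36)
  # CS+ acquisition means rise from early to late block (learning curve)
  bs <- block_summary(tt)
  acq <- bs[bs$session == "acquisition" & bs$cs_type == "CS+", ]
  early <- mean(acq$ampsum_mean[acq$block == "early"])
  late <- mean(acq$ampsum_mean[acq$block == "late"])
  expect_gt(late, early)
})

test_that("HRV conditioning statistics run and skip constant features", {
  set.seed(2)
  trials <- purrr::map_dfr(1:6, function(s) {
    tibble::tibble(
      subject = s,
      session = rep(c("acquisition", "extinction"), each = 18),
      cs_type = rep(rep(c("CS+", "CS-"), each = 9), 2),
      trial = rep(1:9, 4),
      RMSSD = 0.05 + rnorm(36, 0, 0.01) -
        0.004 * (rep(c(0, 1), each = 18) * (rep(rep(c(1, 0), each = 9), 2)) * rep(1:9, 4) / 9),
      HF = 300 + rnorm(36, 0, 40),
      SD1 = 0.04 + rnorm(36, 0, 0.008),
      MNN = 0.85 + rnorm(36, 0, 0.02),
      median_nn = 0.85 + rnorm(36, 0, 0.02),
      RRmean = 0.85 + rnorm(36, 0, 0.02),
      triangular_index = 5 + rnorm(36, 0, 1),
      flatline = 1
    )
  })
  res <- hrv_conditioning_stats(trials, features = c("MNN", "RMSSD", "flatline"))
  expect_true(res$friedman$skipped[res$friedman$feature == "flatline"])
  expect_false(res$friedman$skipped[res$friedman$feature == "MNN"])
  expect_equal(nrow(res$trend), 3)
  expect_true(all(res$trend$n == 6))
})

test_that("extinction vagal decline shows as a negative rank trend", {
  ds <- short_study2(5, seed = 29)
  tt <- build_trial_table(ds)
  res <- hrv_conditioning_stats(tt)
  tr <- res$trend
  expect_true(all(is.finite(tr$mean_rank_slope)))
  expect_lt(mean(tr$mean_rank_slope), 0)
  # latency contrast points the conditioned way on the same dataset
  lat <- latency_stats(tt)
  acq <- lat[lat$comparison == "acquisition: CS+ vs CS-", ]
  expect_gt(acq$mean_1, acq$mean_2)
})

test_that("questionnaire statistics: detection, degenerate and awareness paths", {
  set.seed(3)
  ratings <- tibble::tibble(
    subject = rep(1:11, 2),
    cs_type = rep(c("CS+", "CS-"), each = 11),
    arousal = c(rnorm(11, 4.62, 1.0), rnorm(11, 3.23, 1.0))
  )
  q <- questionnaire_stats(ratings, awareness = rep(4, 11))
  expect_lt(q$arousal_test$p_value, 0.05)
  expect_equal(q$awareness$mean_rating, 4)
  expect_equal(q$awareness$agreement_fraction, 1)

  same <- ratings
  same$arousal <- rep(3, 22)
  q2 <- questionnaire_stats(same)
  expect_equal(q2$arousal_test$p_value, 1)
  expect_error(questionnaire_stats(ratings[1:12, ]), "paired")
})
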