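test_that("grab detection: quiescence, drifting baseline, majority rule", {
  quiet <- synthesize_motion(60, fs = 100, noise_sd = 0.02, seed = 1)
  expect_equal(nrow(detect_grabs(quiet$flexion)), 0)

  m <- synthesize_motion(120, grab_times = c(30, 60, 90), fs = 100,
                         flexion_drift = 1.5, noise_sd = 0.02, seed = 2)
  ev <- detect_grabs(m$flexion)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$time - c(30, 60, 90)) < 0.1))

  # a pulse on one finger only does not satisfy the majority rule
  single <- quiet$flexion
  tt <- single$time
  single$f1 <- single$f1 + ifelse(tt >= 20 & tt <= 20.6,
                                  sin(pi * (tt - 20) / 0.6)^2, 0)
  expect_equal(nrow(detect_grabs(single)), 0)
})

test_that("activity indexes: zeros, white-noise calibration, homogeneity of scale", {
  n <- 100 * 25
  tt <- (0:(n - 1)) / 100
  const <- tibble::tibble(time = tt, x = 1, y = 2, z = 3)
  ai <- activity_indexes(const, const, data.frame(start = 0, end = 25))
  expect_equal(ai$MAI, 0)
  expect_equal(ai$MRI, 0)

  set.seed(3)
  mai <- replicate(50, {
    noise <- tibble::tibble(time = tt, x = rnorm(n), y = rnorm(n), z = rnorm(n))
    activity_indexes(noise, const, data.frame(start = 0, end = 25))$MAI
  })
  expect_equal(mean(mai), 3, tolerance = 0.02)

  set.seed(4)
  noise <- tibble::tibble(time = tt, x = rnorm(n), y = rnorm(n), z = rnorm(n))
  w <- data.frame(start = 0, end = 25)
  a1 <- activity_indexes(noise, const, w)$MAI
  doubled <- dplyr::mutate(noise, x = 2 * x, y = 2 * y, z = 2 * z)
  expect_equal(activity_indexes(doubled, const, w)$MAI, 2 * a1)
  shifted <- dplyr::mutate(noise, x = x + 5, y = y - 2, z = z + 0.1)
  expect_equal(activity_indexes(shifted, const, w)$MAI, a1)

  expect_error(activity_indexes(noise, const, data.frame(start = 0, end = 15)),
               "20 s")
})

test_that("artifact masks pad, merge and measure correctly", {
  timeline <- signal_tbl(numeric(100 * 100), fs = 100)
  empty <- build_artifact_mask(grab_empty_for_test(), timeline)
  expect_false(any(empty$mask))

  grabs <- tibble::tibble(time = c(20, 22.5), duration = c(0.5, 0.5),
                          peak_flexion = c(1, 1))
  m <- build_artifact_mask(grabs, timeline, pad_before = 1, pad_after = 3)
  expect_equal(nrow(m$spans), 1)   # padded spans overlap and merge
  expect_equal(m$spans$start, 19)
  expect_equal(m$spans$end, 26)

  far <- tibble::tibble(time = c(10, 50), duration = c(0.5, 0.5),
                        peak_flexion = c(1, 1))
  m2 <- build_artifact_mask(far, timeline, pad_before = 1, pad_after = 3)
  # masked fraction equals total padded span length over recording length
  expect_equal(mean(m2$mask), 2 * 4.5 / 100, tolerance = 0.005)
  # masking is idempotent: rebuilding from the same spans changes nothing
  m3 <- build_artifact_mask(far, timeline, pad_before = 1, pad_after = 3)
  expect_identical(m2$mask, m3$mask)
  # every grab instant is covered
  expect_true(all(vapply(far$time, function(g) {
    any(m2$time[m2$mask] <= g & g <= m2$time[m2$mask] + 0.011)
  }, logical(1))))
})

test_that("spectral overlap separates shared from disjoint narrowband content", {
  fs <- 100
  tt <- (0:(fs * 30 - 1)) / fs
  a <- signal_tbl(sin(2 * pi * 0.2 * tt), fs = fs)
  expect_equal(spectral_overlap(a, a), 1, tolerance = 1e-9)
  b <- signal_tbl(sin(2 * pi * 1.5 * tt), fs = fs)
  expect_lt(spectral_overlap(a, b), 0.1)
  flat <- signal_tbl(rep(0, length(tt)), fs = fs)
  expect_warning(sc <- spectral_overlap(a, flat), "Degenerate")
  expect_equal(sc, 0)
})

test_that("grab contamination raises the flexion/EDR spectral overlap", {
  wins <- logical(10)
  for (s in 1:10) {
    m <- synthesize_motion(60, grab_times = c(15, 30, 45), fs = 100,
                           artifact_amp = 0.4, seed = s)
    tr <- sudomotor_truth(data.frame(time = 25, amplitude = 0.3),
                          tonic = 2, duration = 60)
    clean <- synthesize_edr(tr, noise_sd = 0.005, seed = 100 + s)
    dirty <- clean
    dirty$value <- dirty$value + m$edr_artifact$value[seq_len(nrow(dirty))]
    attr(dirty, "fs") <- 100
    flex1 <- signal_tbl(m$flexion$f1, fs = 100)
    wins[s] <- spectral_overlap(flex1, dirty) > spectral_overlap(flex1, clean)
  }
  expect_gte(mean(wins), 0.9)
})

test_that("Levene homogeneity testing flags heterogeneity and not homogeneity", {
  set.seed(11)
  # strong variance inequality is detected
  het <- tibble::tibble(
    class = rep(c("A", "B"), each = 30),
    MAI = c(rnorm(30, 1, 0.1), rnorm(30, 1, 1))
  )
  r <- movement_homogeneity(het, "MAI", scope = "between_subject")
  expect_true(r$heterogeneous)

  # identical groups give statistic 0 and p = 1
  v <- rnorm(10)
  same <- tibble::tibble(class = rep(c("A", "B"), each = 10), MAI = c(v, v))
  r2 <- movement_homogeneity(same, "MAI", scope = "between_subject")
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1, tolerance = 1e-12)

  # within-subject scope produces one test per subject
  ws <- tibble::tibble(
    subject = rep(1:3, each = 20),
    class = rep(rep(c("A", "B"), each = 10), 3),
    MAI = rnorm(60)
  )
  r3 <- movement_homogeneity(ws, "MAI", scope = "within_subject")
  expect_equal(nrow(r3), 3)
})

test_that("every synthetic grab is detected and covered by the mask", {
  m <- synthesize_motion(150, grab_times = c(20, 55, 90, 125), fs = 100,
                         flexion_drift = 1, seed = 12)
  ev <- detect_grabs(m$flexion)
  expect_equal(nrow(ev), 4)
  timeline <- signal_tbl(numeric(150 * 100), fs = 100)
  mask <- build_artifact_mask(ev, timeline)
  idx <- vapply(c(20, 55, 90, 125), function(g) {
    any(mask$mask[abs(mask$time - g) < 0.3])
  }, logical(1))
  expect_true(all(idx))
})
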