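test_that("moving-average baseline removal: constants vanish, drift is removed", {
  x <- signal_tbl(rep(3.2, 1000), fs = 250)
  expect_true(all(abs(remove_baseline_maf(x)$value) < 1e-12))

  # 0.05 Hz drift with a 5 s window: attenuation predicted by the MAF
  # frequency-response oracle
  fs <- 250
  tt <- (0:(fs * 60 - 1)) / fs
  drift <- signal_tbl(sin(2 * pi * 0.05 * tt), fs = fs)
  out <- remove_baseline_maf(drift, window = 5)
  gain <- oracle_maf_gain(0.05, round(5 * fs), fs)
  resid_expected <- 1 - gain          # what subtraction of the running mean leaves
  mid <- out$value[(5 * fs):(55 * fs)]
  in_mid <- drift$value[(5 * fs):(55 * fs)]
  expect_lt(mean(mid^2) / mean(in_mid^2), 0.1)
  expect_lt(abs(sqrt(mean(mid^2) / mean(in_mid^2)) - abs(resid_expected)), 0.05)

  # residual of a 0.2 Hz tone under a 0.6 s window matches the oracle too
  slow <- signal_tbl(sin(2 * pi * 0.2 * tt), fs = fs)
  kept <- remove_baseline_maf(slow, window = 0.6)
  g02 <- oracle_maf_gain(0.2, round(0.6 * fs), fs)
  ratio <- sqrt(mean(kept$value[fs:(59 * fs)]^2) / mean(slow$value^2))
  expect_lt(abs(ratio - abs(1 - g02)), 0.02)
  # a QRS-band 5 Hz component passes essentially untouched
  fast <- signal_tbl(sin(2 * pi * 5 * tt), fs = fs)
  keptf <- remove_baseline_maf(fast, window = 0.6)
  expect_gt(mean(keptf$value[fs:(59 * fs)]^2) / mean(fast$value^2), 0.95)

  expect_error(remove_baseline_maf(x, window = 0.001), "3 samples")
})

test_that("degenerate full-length window subtracts the global mean", {
  v <- rnorm(500) + 2
  x <- signal_tbl(v, fs = 100)
  out <- remove_baseline_maf(x, window = 5)
  expect_lt(max(abs(out$value - (v - mean(v)))), 1e-9)
})

test_that("QRS detection recovers noise-free beats to within one sample", {
  rr <- generate_rr_series(120, 60, noise_sd = 0, seed = 2)
  ecg <- synthesize_ecg(rr, fs = 250)
  pk <- detect_qrs_pan_tompkins(ecg)
  expect_equal(length(pk), length(rr$beat_times))
  errs <- vapply(pk, function(p) min(abs(p - rr$beat_times)), numeric(1))
  expect_lt(max(errs), 1 / 250 + 1e-9)
})

test_that("QRS detection stays above 0.99 sensitivity/PPV at 10 dB SNR", {
  sens <- ppv <- numeric(5)
  for (s in 1:5) {
    d <- make_noisy_ecg(100 + s)
    pk <- detect_qrs_pan_tompkins(d$ecg)
    m <- match_events(pk, d$beats)
    sens[s] <- m$sensitivity
    ppv[s] <- m$ppv
  }
  expect_gte(mean(sens), 0.99)
  expect_gte(mean(ppv), 0.99)
})

test_that("flat or empty input yields an empty peak list with a warning", {
  flat <- signal_tbl(rep(0, 250 * 5), fs = 250)
  expect_warning(pk <- detect_qrs_pan_tompkins(flat), "empty")
  expect_length(pk, 0)
})

test_that("RR construction, HR duality and the ectopic neighbor rule", {
  rr <- rr_from_peaks(c(0, 1, 2, 3))
  expect_equal(rr$rr, c(1, 1, 1))
  expect_true(all(rr$nn))
  expect_equal(60 / 0.5, 120)   # HR = 60 / t_RR
  expect_equal(60 / rr$rr, rep(60, 3))

  # a 0.4 s interval amid 1.0 s intervals is flagged non-sinus
  peaks <- c(0, 1, 2, 3, 3.4, 4.4, 5.4, 6.4)
  rr2 <- rr_from_peaks(peaks)
  expect_false(rr2$nn[which.min(rr2$rr)])
  expect_true(all(rr2$nn[-which.min(rr2$rr)]))

  expect_error(rr_from_peaks(1), "2 peaks")
  expect_error(rr_from_peaks(c(1, 1)), "increasing")
})

test_that("Berger resampling preserves constant series and injected frequencies", {
  rr <- rr_from_peaks(0:60)
  tach <- resample_berger(rr, 4)
  expect_true(all(abs(tach$value - 1) < 1e-9))
  # domain: output spans the beat times within one output period
  expect_lt(abs(tach$time[1] - 0), 0.25 + 1e-9)
  expect_lt(abs(max(tach$time) - 60), 0.5 + 1e-9)

  gt <- generate_rr_series(240, 60,
                           modulators = data.frame(freq = 0.1, amp = 0.04),
                           seed = 11)
  tach2 <- resample_berger(rr_from_peaks(gt$beat_times), 4)
  pg <- stats::spec.pgram(stats::ts(tach2$value - mean(tach2$value),
                                    frequency = 4),
                          plot = FALSE, taper = 0)
  f_dom <- pg$freq[which.max(pg$spec)]
  expect_lt(abs(f_dom - 0.1), 4 / nrow(tach2) + 1e-9)
})

test_that("time-domain features match hand computations", {
  td <- time_domain_features(rep(1, 4))
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$NN50, 0L)
  expect_equal(td$pNN50, 0)
  expect_equal(td$MNN, 1)

  td2 <- time_domain_features(c(0.8, 0.9, 0.8, 0.9))
  expect_equal(td2$RMSSD, 0.1)
  expect_equal(td2$pNN50, 100)
  expect_equal(td2$skewness, 0)
  expect_equal(td2$kurtosis_excess, -2)   # two-point symmetric distribution
  expect_equal(td2$HR_mean, mean(60 / c(0.8, 0.9, 0.8, 0.9)))
})

test_that("shift invariance: location moves, dispersion features do not", {
  set.seed(21)
  nn <- 0.8 + cumsum(rnorm(50, 0, 0.01))
  a <- time_domain_features(nn)
  b <- time_domain_features(nn + 0.3)
  expect_equal(b$MNN, a$MNN + 0.3)
  expect_equal(b$SDNN, a$SDNN)
  expect_equal(b$RMSSD, a$RMSSD)
  pa <- poincare_features(nn)
  pb <- poincare_features(nn + 0.3)
  expect_equal(pa$SD1, pb$SD1)
  expect_equal(pa$SD2, pb$SD2)
  ga <- geometric_features(nn)
  gb <- geometric_features(nn + 0.3)
  expect_equal(ga$triangular_index, gb$triangular_index)
})

test_that("geometric features: degenerate and uniform histograms", {
  g <- geometric_features(rep(0.9, 30))
  expect_equal(g$triangular_index, 1)
  expect_lte(g$TINN, 3 / 128)
  # uniform occupancy of k bins with c entries each -> index = k
  bw <- 1 / 128
  k <- 5
  nn <- rep(bw * (0:(k - 1)) + 0.8 + bw / 2, each = 4)
  gu <- geometric_features(nn, bin_width = bw)
  expect_equal(gu$triangular_index, k)
})

test_that("spectral band attribution: 0.1 Hz -> LF, 0.25 Hz -> HF", {
  lf_rr <- generate_rr_series(300, 60,
                              modulators = data.frame(freq = 0.1, amp = 0.03),
                              seed = 31)
  ff <- frequency_features(resample_berger(rr_from_peaks(lf_rr$beat_times), 4))
  expect_gt(ff$LF / (ff$VLF + ff$LF + ff$HF), 0.9)

  hf_rr <- generate_rr_series(300, 60,
                              modulators = data.frame(freq = 0.25, amp = 0.03),
                              seed = 32)
  ff2 <- frequency_features(resample_berger(rr_from_peaks(hf_rr$beat_times), 4))
  expect_gt(ff2$HF / (ff2$VLF + ff2$LF + ff2$HF), 0.9)
  expect_true(ff2$HF_reliable)
})

test_that("white-noise tachogram spreads power roughly by bandwidth", {
  set.seed(41)
  fracs <- replicate(20, {
    tach <- signal_tbl(rnorm(1200, 1, 0.05), fs = 4)
    ff <- frequency_features(tach)
    c(ff$LF, ff$HF) / (ff$LF + ff$HF)
  })
  # LF/HF bandwidth ratio is 0.11/0.25
  expect_equal(mean(fracs[1, ]), 0.11 / 0.36, tolerance = 0.05)
  expect_equal(mean(fracs[2, ]), 0.25 / 0.36, tolerance = 0.05)
})

test_that("Poincare dispersions: constant, identity, and alternating series", {
  expect_equal(poincare_features(rep(0.8, 10)),
               tibble::tibble(SD1 = 0, SD2 = 0))
  set.seed(5)
  for (i in 1:10) {
    nn <- 0.9 + rnorm(60, 0, 0.03)
    pc <- poincare_features(nn)
    # SD1^2 = half the variance of successive differences (rotation oracle)
    d <- diff(nn)
    rot <- sd(d / sqrt(2))
    expect_lt(abs(pc$SD1 - rot), 1e-12)
    expect_lt(abs(pc$SD1^2 + pc$SD2^2 - 2 * var(nn)), 1e-12)
  }
  # alternating a,b: SD1 = |a-b|/sqrt(2) under the sample-variance convention
  nn <- rep(c(0.8, 0.9), 20)
  pc <- poincare_features(nn)
  d <- diff(nn)
  expect_equal(pc$SD1, sd(d) / sqrt(2))
  expect_lt(pc$SD2, pc$SD1 / 3)
  expect_error(poincare_features(c(1, 2)), "3 intervals")
})

test_that("approximate entropy agrees with the brute-force oracle", {
  expect_equal(entropy_feature(rep(1, 30)), 0)
  set.seed(6)
  for (i in 1:3) {
    x <- rnorm(80, 1, 0.05)
    r <- 0.2 * sd(x)
    expect_lt(abs(entropy_feature(x, m = 2, r_frac = 0.2) -
                    oracle_apen(x, 2, r)), 1e-9)
  }
})

test_that("regular series carry less entropy than their shuffles", {
  set.seed(61)
  wins <- replicate(10, {
    base <- rep(c(0.8, 0.9), 30) + rnorm(60, 0, 0.002)
    shuf <- sample(base)
    entropy_feature(base) < entropy_feature(shuf)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("windowed HRV features respect the 20 s floor and slice consistently", {
  gt <- generate_rr_series(70, 70, noise_sd = 0.01, seed = 71)
  rr <- rr_from_peaks(gt$beat_times)
  out <- hrv_window_features(rr, data.frame(start = c(0, 30), end = c(30, 60)))
  expect_equal(nrow(out), 2)
  expect_error(
    hrv_window_features(rr, data.frame(start = 0, end = 19)),
    "20 s"
  )
  # window features equal a direct call on the manually sliced sub-series
  sel <- rr$onset >= 0 & (rr$onset + rr$rr) <= 30
  sub <- rr[sel, ]
  class(sub) <- class(rr)
  direct <- hrv_features(sub)
  expect_equal(out$MNN[1], direct$MNN)
  expect_equal(out$RMSSD[1], direct$RMSSD)
  expect_equal(out$SD1[1], direct$SD1)
})
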