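test_that("zero-phase low-pass: DC gain 1, stop-band rejection, no delay", {
  fs <- 100
  tt <- (0:(fs * 30 - 1)) / fs
  dc <- signal_tbl(rep(1.5, length(tt)), fs = fs)
  expect_lt(max(abs(lowpass_zero_phase(dc)$value - 1.5)), 1e-6)

  tone <- signal_tbl(sin(2 * pi * 10 * tt), fs = fs)
  out <- lowpass_zero_phase(tone, cutoff = 2)
  expect_lt(sqrt(mean(out$value[500:2500]^2)) / sqrt(mean(tone$value^2)), 0.05)

  # peak of a smooth pulse is not shifted
  pulse <- signal_tbl(exp(-(tt - 15)^2 / 0.5), fs = fs)
  pf <- lowpass_zero_phase(pulse, cutoff = 2)
  expect_lte(abs(pf$time[which.max(pf$value)] - 15), 1 / fs + 1e-9)

  expect_error(lowpass_zero_phase(dc, cutoff = 60), "Nyquist")
})

test_that("Bateman IRF obeys its defining properties", {
  expect_equal(bateman_irf(0), 0)
  expect_equal(bateman_irf(-3), 0)
  expect_true(all(bateman_irf(seq(0.01, 30, by = 0.01)) > 0))
  expect_lt(bateman_irf(60), 1e-10)
  # argmax equals tau1*tau2/(tau1-tau2)*log(tau1/tau2) (calculus oracle)
  for (p in list(c(2, 0.75), c(4, 1), c(1.5, 0.3))) {
    t_star <- p[1] * p[2] / (p[1] - p[2]) * log(p[1] / p[2])
    opt <- stats::optimize(function(t) bateman_irf(t, p[1], p[2]),
                           c(0, 20), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(opt$maximum - t_star), 1e-6)
  }
  expect_error(bateman_irf(1, 1, 1), "tau1 > tau2")
})

test_that("noise-free decomposition recovers impulse area, time and count", {
  tr <- sudomotor_truth(data.frame(time = 25, amplitude = 0.5), tonic = 0,
                        duration = 60)
  dec <- deconvolve_edr(synthesize_edr(tr))
  area <- sum(dec$signal$driver) / dec$fs
  expect_lt(abs(area - 0.5) / 0.5, 0.01)
  expect_equal(nrow(dec$scr_events), 1)
  expect_lt(abs(dec$scr_events$peak_time - 25), 0.1)
  # reconstruction: tonic + reconvolved driver reproduces the input
  recon <- dec$signal$tonic + dec$signal$phasic
  expect_lt(max(abs(recon - dec$signal$edr)), 1e-9)
})

test_that("constant input decomposes into pure tonic", {
  dec <- deconvolve_edr(signal_tbl(rep(2.4, 100 * 40), fs = 100, units = "uS"))
  expect_lt(max(abs(dec$signal$tonic - 2.4)), 1e-6)
  expect_lt(max(abs(dec$signal$driver)), 1e-6)
  expect_equal(nrow(dec$scr_events), 0)
})

test_that("overlapping responses 1.5 s apart resolve into two driver peaks", {
  tr <- sudomotor_truth(data.frame(time = c(20, 21.5), amplitude = c(0.4, 0.3)),
                        tonic = 1, duration = 50)
  dec <- deconvolve_edr(synthesize_edr(tr))
  expect_equal(nrow(dec$scr_events), 2)
  expect_lt(abs(dec$scr_events$peak_time[1] - 20), 0.1)
  expect_lt(abs(dec$scr_events$peak_time[2] - 21.5), 0.1)
})

test_that("decomposition rejects too-short recordings", {
  expect_error(deconvolve_edr(signal_tbl(rep(1, 100 * 5), fs = 100)),
               "at least")
})

test_that("SCR significance threshold filters small responses", {
  tr <- sudomotor_truth(
    data.frame(time = c(20, 40), amplitude = c(0.3, 0.005)),
    tonic = 1, duration = 60
  )
  dec <- deconvolve_edr(synthesize_edr(tr))
  ev <- detect_scrs(dec, min_amplitude = 0.01)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_time - 20), 0.1)
})

test_that("well-separated impulses are each recovered (20 seeds)", {
  ok <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 5
    times <- sort(runif(n, 10, 75))
    while (any(diff(times) < 2.5)) times <- sort(runif(n, 10, 75))
    amps <- runif(n, 0.1, 0.5)
    tr <- sudomotor_truth(data.frame(time = times, amplitude = amps),
                          tonic = 2, duration = 85)
    dec <- deconvolve_edr(synthesize_edr(tr))
    ok[s] <- nrow(dec$scr_events) == n
  }
  expect_true(all(ok))
})

test_that("increasing an impulse amplitude never decreases AmpSum", {
  amps <- c(0.1, 0.2, 0.35, 0.5)
  res <- vapply(amps, function(a) {
    tr <- sudomotor_truth(data.frame(time = 21.5, amplitude = a),
                          tonic = 1, duration = 50)
    dec <- deconvolve_edr(synthesize_edr(tr))
    phasic_features(dec, 20, window_len = 5)$AmpSum
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("phasic windows: empty case, ground-truth event, latency gate", {
  tr <- sudomotor_truth(data.frame(time = 31.5, amplitude = 0.4),
                        tonic = 1.5, duration = 70)
  dec <- deconvolve_edr(synthesize_edr(tr))

  none <- phasic_features(dec, 5, window_len = 5)
  expect_equal(none$nSCR, 0)
  expect_equal(none$AmpSum, 0)
  expect_true(is.na(none$Lat))

  hit <- phasic_features(dec, 30, window_len = 5, min_latency = 1)
  expect_equal(hit$nSCR, 1)
  expect_lt(abs(hit$Lat - 1.5), 0.35)      # onset of the reconvolved response
  expect_lt(abs(hit$AmpSum - 0.4 * max(bateman_irf(seq(0, 20, 0.01)))) / hit$AmpSum,
            0.25)

  # an impulse 0.5 s post-onset is excluded by the 1 s latency gate
  tr2 <- sudomotor_truth(data.frame(time = 30.5, amplitude = 0.4),
                         tonic = 1.5, duration = 70)
  dec2 <- deconvolve_edr(synthesize_edr(tr2))
  gated <- phasic_features(dec2, 30, window_len = 5, min_latency = 1)
  expect_equal(gated$nSCR, 0)

  expect_error(phasic_features(dec, 68, window_len = 5), "outside")
})

test_that("tonic features: flat level, ramp mean, non-specific counting", {
  flat <- deconvolve_edr(signal_tbl(rep(2, 100 * 40), fs = 100))
  tf <- tonic_features(flat)
  expect_lt(abs(tf$Mean_Tonic - 2), 1e-6)
  expect_lt(tf$Var_Tonic, 1e-10)
  expect_equal(tf$NSR, 0)

  ramp <- sudomotor_truth(NULL, tonic = data.frame(time = c(0, 60), level = c(1, 3)),
                          duration = 60)
  dr <- deconvolve_edr(synthesize_edr(ramp))
  expect_lt(abs(tonic_features(dr)$Mean_Tonic - 2), 0.02)

  # 3 impulses between the stimulus windows count as non-specific
  tr <- sudomotor_truth(
    data.frame(time = c(15, 35, 55, 75), amplitude = c(0.3, 0.3, 0.3, 0.3)),
    tonic = 2, duration = 90
  )
  dec <- deconvolve_edr(synthesize_edr(tr))
  tf2 <- tonic_features(dec, data.frame(start = 74, end = 80))
  expect_equal(tf2$NSR, 3)
})
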