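test_that("decimation halves the rate and preserves the passband", {
  fs <- 1000
  tt <- (0:9999) / fs
  s <- ecg_signal(sin(2 * pi * 5 * tt), fs)
  d <- decimate_signal(s, 2)
  expect_equal(d$fs, 500)
  expect_equal(length(d$samples), 5000)
  # amplitude of the 5 Hz tone preserved within 1% (away from the edges)
  expect_lt(abs(max(abs(d$samples[500:4500])) - 1), 0.01)
  expect_identical(decimate_signal(s, 1), s)
  expect_error(decimate_signal(s, 0), "factor")
  r <- resp_signal(sin(2 * pi * 0.25 * tt), fs)
  expect_equal(decimate_signal(r, 10)$fs, 100)
})

test_that("Pan-Tompkins recovers synthetic beats and rejects flat signals", {
  p <- trait_profile(mean_nn = 1000, nn_sd = 0, rsa_amplitude = 0)
  rr <- simulate_rr_series(p, 30, seed = 1)
  e <- synthesize_ecg(rr$beat_times, fs = 500, snr = Inf, duration = 30)
  b <- detect_r_peaks(e$ecg)
  expect_equal(length(b$r_times), length(rr$beat_times))
  expect_lt(max(abs(b$r_times - rr$beat_times)), 0.010)

  p2 <- trait_profile(mean_nn = 750, nn_sd = 20, rsa_amplitude = 15)
  rr2 <- simulate_rr_series(p2, 90, seed = 2)
  e2 <- synthesize_ecg(rr2$beat_times, fs = 500, snr = 15, duration = 90, seed = 3)
  b2 <- detect_r_peaks(e2$ecg)
  expect_lte(abs(length(b2$r_times) - 121), 1)

  flat <- ecg_signal(rep(0, 5000), 500)
  expect_warning(bf <- detect_r_peaks(flat), "flat")
  expect_length(bf$r_times, 0)
  expect_error(detect_r_peaks(ecg_signal(rnorm(100), 100)), "fs")
})

test_that("3-SD RR cleaning matches the hand rule and is idempotent", {
  # constant series: untouched
  ct <- cumsum(rep(0.8, 20))
  nn0 <- clean_rr(ct)
  expect_equal(nn0$intervals, rep(800, 19))
  expect_false(any(nn0$artifact_flags))

  # one large outlier is flagged and replaced by its neighbors' mean
  set.seed(4)
  iv <- 800 + rnorm(40, 0, 10)
  iv[20] <- 3000
  beats <- cumsum(c(0, iv)) / 1000
  nn <- clean_rr(beats)
  expect_true(nn$artifact_flags[20])
  expect_equal(sum(nn$artifact_flags), 1)
  expect_equal(nn$intervals[20], mean(iv[c(19, 21)]), tolerance = 1e-12)

  # interleaved outliers are both caught in the same single pass
  iv2 <- rep(c(800, 810), 20)
  iv2[c(10, 25)] <- c(2500, 2600)
  res <- oracle_clean(iv2)
  nn2 <- clean_rr(cumsum(c(0, iv2)) / 1000)
  expect_equal(which(nn2$artifact_flags), which(res$flags))
  expect_equal(nn2$intervals, res$values, tolerance = 1e-9)

  # idempotence: re-cleaning the cleaned series changes nothing
  nn3 <- clean_rr(cumsum(c(0, nn2$intervals)) / 1000)
  expect_equal(nn3$intervals, nn2$intervals, tolerance = 1e-9)
  expect_false(any(nn3$artifact_flags))

  expect_error(clean_rr(c(0, 0.8, 1.6)), "4 beats")
})

test_that("HRV formulas match their stated values and the brute-force oracles", {
  expect_equal(rmssd(c(800, 810, 800)), 10)
  expect_equal(rmssd(c(800, 820, 800, 820)), 20)
  expect_equal(sdnn(c(700, 900)), sqrt(2) * 100, tolerance = 1e-9)
  expect_equal(heart_rate(c(600, 1000)), 75)
  expect_equal(heart_rate(rep(1000, 10)), 60)
  expect_equal(heart_rate(rep(500, 10)), 120)
  expect_equal(hrv_ti(rep(800.1, 30)), 1)
  # 30 intervals spread over 3 bins, 10 each
  x3 <- rep(c(801, 809, 817), 10)
  expect_equal(hrv_ti(x3), 3)
  expect_equal(rmssd(rep(777, 10)), 0)
  expect_equal(sdnn(rep(777, 10)), 0)

  for (s in 1:25) {
    x <- random_nn(60, s)
    expect_equal(rmssd(x), oracle_rmssd(x), tolerance = 1e-9)
    expect_equal(sdnn(x), oracle_sdnn(x), tolerance = 1e-9)
    expect_equal(hrv_ti(x), oracle_hrvti(x), tolerance = 1e-9)
    expect_equal(heart_rate(x), oracle_hr(x), tolerance = 1e-9)
  }
  expect_error(rmssd(c(800, 810)), "3 intervals")
  expect_error(sdnn(800), "2 intervals")
})

test_that("shift invariance: +50 ms moves HR only, per closed form", {
  x <- random_nn(50, 7)
  expect_equal(rmssd(x + 50), rmssd(x), tolerance = 1e-9)
  expect_equal(sdnn(x + 50), sdnn(x), tolerance = 1e-9)
  expect_equal(heart_rate(x + 50), 60000 / (mean(x) + 50), tolerance = 1e-9)
})

test_that("respiration rate recovery and out-of-band flagging", {
  r15 <- simulate_respiration(15, 90, 100, noise_sd = 0, seed = 1)
  est <- respiration_rate(r15)
  expect_lt(abs(est - 15), 0.7)

  # below-band input is flagged missing
  oob <- simulate_respiration(3, 90, 100, noise_sd = 0, seed = 1)
  expect_warning(lo <- respiration_rate(oob))
  expect_true(is.na(lo))

  for (r in c(12, 19, 27, 33, 40)) {
    s <- simulate_respiration(r, 90, 100, noise_sd = 0.05, seed = r)
    expect_lt(abs(respiration_rate(s) - r), 0.5)
  }
  expect_error(respiration_rate(resp_signal(rnorm(100), 20)), "fs")
})

test_that("segment summaries split 90 s into 30-s blocks and flag sparse blocks", {
  p <- trait_profile(mean_nn = 800, nn_sd = 20, rsa_amplitude = 10)
  rr <- simulate_rr_series(p, 90, seed = 5)
  nn <- nn_series(rr$nn, onset_times = rr$beat_times[-length(rr$beat_times)])
  resp <- simulate_respiration(14, 90, 100, seed = 6)
  sm <- segment_summary(nn, resp)
  expect_equal(nrow(sm), 3)
  expect_equal(sm$start, c(0, 30, 60))
  expect_false(any(sm$missing))

  # a single whole-session segment equals whole-recording metrics
  sm1 <- segment_summary(nn, resp, segments = list(c(0, 90)))
  expect_equal(sm1$rmssd, rmssd(rr$nn), tolerance = 1e-9)
  expect_equal(sm1$sdnn, sdnn(rr$nn), tolerance = 1e-9)
  expect_equal(sm1$hr, heart_rate(rr$nn), tolerance = 1e-9)
  expect_lt(abs(sm1$rr - 14), 0.7)

  # block containing too few beats is missing-flagged
  nn2 <- nn_series(c(800, 820, 810), onset_times = c(0, 0.8, 1.62))
  sm2 <- segment_summary(nn2, NULL, segments = list(c(0, 2), c(2, 4)))
  expect_false(sm2$missing[1])
  expect_true(sm2$missing[2])
  expect_true(is.na(sm2$rmssd[2]))
  expect_error(segment_summary(nn2, NULL, segments = list()), "non-empty")
  expect_error(segment_summary(nn2, NULL,
                               segments = list(c(0, 2), c(1, 3))), "overlap")
})
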