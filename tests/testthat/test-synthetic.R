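# local helper mirroring the package's center-zone test
in_center_zone_test <- function(g, x, y) {
  cz <- g$center_zone
  x >= cz["x1"] & x <= cz["x2"] & y >= cz["y1"] & y <= cz["y2"]
}

test_that("trajectory generator honors thigmotaxis, geometry and determinism", {
  g <- scene_geometry("empty_room")

  # full wall bias keeps >= 90% of samples within 0.5 m of a wall
  p1 <- trait_profile(thigmotaxis_bias = 1, gait_speed_cv = 0.2)
  tr <- simulate_trajectory(p1, g, 90, 90, seed = 4)
  wd <- pmin(tr$x, g$room_width - tr$x, tr$y, g$room_length - tr$y)
  expect_gte(mean(wd <= 0.5), 0.9)

  # unbiased long walk spends roughly the center's area share in the center
  p0 <- trait_profile(thigmotaxis_bias = 0, center_avoidance = 0)
  tr0 <- simulate_trajectory(p0, g, 600, 30, seed = 5)
  frac <- mean(in_center_zone_test(g, tr0$x, tr0$y))
  expect_lt(abs(frac - 0.25), 0.08)

  # zero speed pins the subject to the start point
  trs <- simulate_trajectory(p0, g, 10, 90, seed = 1, mean_speed = 0)
  expect_true(all(trs$x == trs$x[1] & trs$y == trs$y[1]))

  # containment, both scenes
  expect_true(all(tr$x >= 0 & tr$x <= 3.5 & tr$y >= 0 & tr$y <= 6))
  ga <- scene_geometry("elevated_alley")
  tra <- simulate_trajectory(trait_profile(center_avoidance = 0.2), ga, 90, 90,
                             seed = 6)
  hw <- stresswalk:::half_width_at(ga, tra$y)
  expect_true(all(abs(tra$x - 1.75) <= hw + 1e-9))

  # determinism
  expect_identical(simulate_trajectory(p1, g, 30, 90, seed = 9),
                   simulate_trajectory(p1, g, 30, 90, seed = 9))
  expect_error(simulate_trajectory(p1, g, -1, 90, seed = 1), "duration")
  expect_error(simulate_trajectory(p1, g, 10, 5, seed = 1), "rate")
})

test_that("geometry constructor validates the stated scene dimensions", {
  g <- scene_geometry("empty_room")
  expect_equal(g$room_width, 3.5)
  expect_equal(g$room_length, 6.0)
  cz <- g$center_zone
  expect_true(cz["x1"] > 0 && cz["x2"] < 3.5 && cz["y1"] > 0 && cz["y2"] < 6)
  ga <- scene_geometry("elevated_alley")
  expect_equal(ga$alley_patches$width, c(3.5, 2.5, 1.5, 0.5))
  expect_error(scene_geometry(patch_widths = c(1, 2, 3)), "decreasing")
  expect_error(trait_profile(thigmotaxis_bias = 1.2), "thigmotaxis")
  expect_error(trait_profile(resp_rate = 5), "resp_rate")
})

test_that("RR series generator matches its closed-form contracts", {
  # deterministic 1000 ms beats: 90 identical intervals, zero RMSSD truth
  p <- trait_profile(mean_nn = 1000, nn_sd = 0, rsa_amplitude = 0)
  rr <- simulate_rr_series(p, 90, seed = 1)
  expect_equal(length(rr$nn), 90)
  expect_true(all(rr$nn == 1000))
  expect_equal(rr$beat_times, 0:90)

  # beat count arithmetic at 750 ms
  p2 <- trait_profile(mean_nn = 750, nn_sd = 0, rsa_amplitude = 0)
  expect_lte(abs(length(simulate_rr_series(p2, 90, seed = 1)$nn) - 120), 1)

  # with no AR memory, sample SDNN of the truth concentrates on nn_sd
  p3 <- trait_profile(mean_nn = 800, nn_sd = 40, rsa_amplitude = 0)
  sds <- vapply(1:200, function(s) {
    sd(simulate_rr_series(p3, 90, seed = s, ar_coef = 0)$nn)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 40), 2)

  expect_error(simulate_rr_series(trait_profile(mean_nn = 900), 1), "duration")
})

test_that("ECG synthesis places R waves on the sample grid", {
  beats <- 0:9
  out <- synthesize_ecg(beats, fs = 500, snr = Inf, duration = 10)
  expect_equal(length(out$ecg$samples), 5000)
  # waveform maxima sit at the true beat samples (index b*500 + 1)
  for (b in 1:8) {
    win <- (b * 500 - 100):(b * 500 + 100)
    expect_equal(win[which.max(out$ecg$samples[win])], b * 500 + 1)
  }
  expect_equal(out$beat_index, beats * 500 + 1)
  expect_error(synthesize_ecg(numeric(0), 500), "non-empty")
  expect_error(synthesize_ecg(0:5, fs = 100), "fs")
})

test_that("respiration generator has the stated cycle count and rate", {
  r <- simulate_respiration(15, 90, 100, noise_sd = 0, seed = 1)
  expect_equal(length(r$samples), 9000)
  # 22.5 cycles -> 22 or 23 zero-up-crossings of the sinusoid
  ups <- sum(diff(r$samples > 0) == 1)
  expect_lte(abs(ups - 22.5), 0.5)
  expect_equal(attr(r, "true_rate"), 15)
  expect_error(simulate_respiration(-1, 90, 100), "resp_rate")
})

test_that("gait generator produces the scripted stride rate and truth", {
  p <- trait_profile()
  # constant 1 m/s walk, stride 0.7 m -> ~1.43 same-foot strikes per second
  tt <- seq(0, 40, by = 1 / 90)
  ht <- data.frame(t = tt, x = 1.75, y = pmin(0.3 + tt, 5.7), z = 1.7, yaw = 90)
  ht$y <- 0.3 + (tt %% 10) * 0  # overwritten below
  ht$y <- pmin(0.3 + tt * 1.0, 5.7)
  g <- simulate_gait(ht, p, seed = 2)
  walk_end <- 5.4  # reaches the far end after ~5.4 s
  rate_l <- sum(g$heel_strikes$left < walk_end) / walk_end
  expect_lt(abs(rate_l - 1.43), 0.35)

  # stationary head -> no step events, feet flat
  hs <- pin_traj(1.75, 3, duration = 10, rate = 90)
  gs <- simulate_gait(hs, p, seed = 3)
  expect_length(gs$heel_strikes$left, 0)
  expect_length(gs$heel_strikes$right, 0)
  expect_true(all(gs$left$z == 0))

  expect_identical(simulate_gait(ht, p, seed = 2), g)
})

test_that("cohort generation couples physiology to the latent trait", {
  co <- generate_cohort(12, coupling = 1, seed = 5)
  expect_identical(co, generate_cohort(12, coupling = 1, seed = 5))
  expect_error(generate_cohort(1), "n must be")

  tr <- cohort_truth(co)
  expect_true(all(is.finite(tr$rmssd3_true)))
  expect_true(all(tr$stai_t >= 20 & tr$stai_t <= 60))

  # all recordings contained and complete
  s1 <- co[[1]]$sessions$empty_room
  expect_s3_class(s1, "session_recording")
  expect_true(all(s1$head_track$x >= 0 & s1$head_track$x <= 3.5))
  expect_equal(s1$ecg$fs, 500)
  expect_equal(s1$respiration$fs, 100)
  expect_length(co[[1]]$sessions$dark_maze$truth$nn,
                length(co[[1]]$sessions$dark_maze$truth$beat_times) - 1)
})

test_that("coupling strength controls the vulnerability-RMSSD association", {
  # closed-form maps at n = 140: strong coupling gives |rank cor| >= 0.8,
  # and the association is negative (vagal withdrawal)
  set.seed(42)
  v <- rnorm(140)
  nn_sd_base <- pmax(45 + rnorm(140, 0, 6), 10)
  rsa_base <- pmax(28 + rnorm(140, 0, 4), 5)
  strong <- stresswalk:::trait_maps(v, 1, 900, nn_sd_base, rsa_base)
  rho <- cor(v, strong$nn_sd3, method = "spearman")
  expect_lt(rho, -0.8)

  # sampled truth at modest n agrees in sign and magnitude
  co <- generate_cohort(40, coupling = 1, seed = 7)
  tr <- cohort_truth(co)
  expect_lt(cor(tr$vulnerability, tr$rmssd3_true, method = "spearman"), -0.8)

  # no coupling: association indistinguishable from zero
  co0 <- generate_cohort(40, coupling = 0, seed = 8)
  tr0 <- cohort_truth(co0)
  expect_lt(abs(cor(tr0$vulnerability, tr0$rmssd3_true, method = "spearman")),
            0.35)
  # STAI-T independent of vulnerability by construction
  expect_lt(abs(cor(tr$vulnerability, tr$stai_t)), 0.4)
})
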