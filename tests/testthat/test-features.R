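er_geom <- scene_geometry("empty_room")
ea_geom <- scene_geometry("elevated_alley")

test_that("empty-room position features on pinned trajectories", {
  # pinned at a corner: zero corner distance, no center time
  corner <- pin_traj(0, 0)
  f <- position_features_er(corner, er_geom)
  expect_equal(unname(f["corner_dist_min"]), 0)
  expect_equal(unname(f["time_center"]), 0)

  # pinned at the room center: nearest-corner distance from plane geometry
  center <- pin_traj(1.75, 3.0)
  fc <- position_features_er(center, er_geom)
  expect_equal(unname(fc["corner_dist_min"]), sqrt(1.75^2 + 3^2),
               tolerance = 1e-9)

  # entirely inside the center zone: periphery 0, ratio capped and flagged
  expect_equal(unname(fc["time_periphery"]), 0)
  expect_true(attr(fc, "capped"))
  expect_equal(unname(fc["ratio_center_periphery"]),
               (max(center$t) - min(center$t)) / median(diff(center$t)))

  out_of_room <- pin_traj(5, 3)
  expect_error(position_features_er(out_of_room, er_geom), "bounds")
})

test_that("elevated-alley features follow the scripted traverse", {
  # subject never leaves the board
  board <- pin_traj(1.75, 0.5)
  fb <- position_features_ea(board, ea_geom)
  expect_equal(unname(fb["time_board"]), max(board$t) - min(board$t))
  expect_equal(unname(fb["time_narrow"]), 0)
  expect_equal(unname(fb["max_y"]), 0.5)
  # never-crossed thresholds are right-censored at the session length
  expect_equal(unname(fb["cross_time1"]), 30)

  # scripted full traverse at 0.5 m/s: crossing times = distance / speed
  tt <- seq(0, 14, by = 1 / 90)
  trav <- data.frame(t = tt, x = 1.75, y = pmin(0.5 * tt, 5.95), z = 1.7, yaw = 90)
  ftv <- position_features_ea(trav, ea_geom)
  expect_equal(unname(ftv[c("cross_time1", "cross_time2", "cross_time3")]),
               c(1.5, 3.0, 4.5) / 0.5, tolerance = 0.02)
  expect_gt(unname(ftv["max_y"]), 5.9)
  expect_equal(unname(ftv["n_retreats"]), 0)
  # patch dwell times sum to the total session time
  expect_equal(sum(ftv[paste0("time_patch", 1:4)]),
               (max(tt) - min(tt)), tolerance = 0.05)

  # a single 0.5 m retreat is counted once
  tt2 <- seq(0, 20, by = 1 / 90)
  y2 <- ifelse(tt2 < 8, 0.5 * tt2, ifelse(tt2 < 10, 4 - 0.25 * (tt2 - 8), 3.5))
  ret <- data.frame(t = tt2, x = 1.75, y = y2, z = 1.7, yaw = 90)
  expect_equal(unname(position_features_ea(ret, ea_geom)["n_retreats"]), 1)
})

test_that("kinematics match closed forms", {
  still <- pin_traj(1, 1)
  ks <- kinematics_features(still)
  expect_equal(unname(ks["speed_mean"]), 0)
  expect_equal(unname(ks["vert_acc_rms"]), 0)

  tt <- seq(0, 20, by = 1 / 90)
  line <- data.frame(t = tt, x = 0.5 + 0.1 * tt, y = 0.5 + pmin(tt, 5),
                     z = 1.7, yaw = 90)
  line$y <- 0.5 + 0.2 * tt
  kl <- kinematics_features(line)
  expect_equal(unname(kl["speed_mean"]), sqrt(0.1^2 + 0.2^2), tolerance = 1e-3)
  expect_lt(unname(kl["acc_rms"]), 0.01)

  # z(t) = A sin(2 pi f t): RMS vertical acceleration = A (2 pi f)^2 / sqrt(2)
  A <- 0.05; f <- 1.2
  bob <- data.frame(t = tt, x = 1, y = 1 + 0.3 * tt,
                    z = 1.7 + A * sin(2 * pi * f * tt), yaw = 90)
  kb <- kinematics_features(bob, smooth_window = 0)
  expect_equal(unname(kb["vert_acc_rms"]), A * (2 * pi * f)^2 / sqrt(2),
               tolerance = 0.02)
})

test_that("focus and concentric shape features behave at their extremes", {
  one_cell <- pin_traj(1.1, 1.1)
  fs <- trajectory_shape_features(one_cell, er_geom)
  expect_equal(unname(fs["focus"]), 1)

  # equal dwell over many cells: focus near 0
  cells_x <- rep(seq(0.125, 3.375, by = 0.25), times = 10)
  cells_y <- rep(seq(0.125, 2.375, by = 0.25), each = 14)
  grid_traj <- data.frame(t = seq_along(cells_x) * 0.1, x = cells_x,
                          y = cells_y, z = 1.7, yaw = 0)
  fg <- trajectory_shape_features(grid_traj, er_geom)
  expect_lt(unname(fg["focus"]), 0.05)

  # circular path around the room center is fully concentric
  th <- seq(0, 6 * pi, length.out = 2000)
  circ <- data.frame(t = seq_along(th) * 0.02, x = 1.75 + 1.2 * cos(th),
                     y = 3 + 1.2 * sin(th), z = 1.7, yaw = 0)
  fcir <- trajectory_shape_features(circ, er_geom)
  expect_gt(unname(fcir["concentric"]), 0.99)

  # straight radial path is not concentric
  rad <- data.frame(t = seq(0, 10, by = 1 / 50))
  rad$x <- 1.75; rad$y <- 0.5 + 0.5 * rad$t; rad$z <- 1.7; rad$yaw <- 90
  expect_lt(unname(trajectory_shape_features(rad, er_geom)["concentric"]), 0.01)
})

test_that("head scans are counted only while walking", {
  tt <- seq(0, 60, by = 1 / 90)
  walk <- data.frame(t = tt, x = 1.75, y = 0.3 + 0.08 * tt, z = 1.7)
  walk$y <- 0.3 + 0.5 * tt * (tt < 10) + 5 * (tt >= 10)
  walk$y <- pmin(walk$y, 5.8)
  heading <- 90  # walking along +y
  yaw <- rep(heading, length(tt))
  # five scripted 40-degree excursions of 1 s while moving (t < 10)
  onsets <- c(1, 3, 5, 7, 9)
  for (o in onsets) yaw[tt >= o & tt < o + 1] <- heading + 40
  walk$yaw <- yaw
  f <- head_scan_count(walk)
  expect_equal(unname(f["head_scans"]), 5)

  # same excursions while stationary count zero
  still <- pin_traj(1.75, 3, duration = 60, rate = 90)
  yaw2 <- rep(90, nrow(still))
  for (o in onsets) yaw2[still$t >= o & still$t < o + 1] <- 130
  still$yaw <- yaw2
  expect_equal(unname(head_scan_count(still)["head_scans"]), 0)

  # yaw locked to heading: no scans
  locked <- walk; locked$yaw <- rep(90, nrow(walk))
  expect_equal(unname(head_scan_count(locked)["head_scans"]), 0)

  # generator truth round-trip: scripted scan onsets are recovered
  p <- trait_profile(vulnerability = -1, thigmotaxis_bias = 0.3,
                     center_avoidance = 0.2, gait_speed_cv = 0.1)
  tr <- simulate_trajectory(p, er_geom, 90, 90, seed = 21)
  n_true <- length(attr(tr, "scan_times"))
  n_det <- unname(head_scan_count(tr)["head_scans"])
  expect_lte(abs(n_det - n_true), max(1, 0.3 * n_true))
})

test_that("gait cycle detection recovers scripted and generated strides", {
  p <- trait_profile()
  tt <- seq(0, 40, by = 1 / 90)
  ht <- data.frame(t = tt, x = 1.75, y = pmin(0.3 + tt, 5.7), z = 1.7, yaw = 90)
  g <- simulate_gait(ht, p, seed = 2)
  ev <- detect_gait_cycles(g[c("left", "right")])
  truth <- sort(unlist(g$heel_strikes))
  det <- sort(unlist(ev$heel_strikes))
  hit <- mean(vapply(truth, function(s) any(abs(det - s) < 0.1), logical(1)))
  expect_gte(hit, 0.95)
  # constant-speed script: stride speed CV near zero
  expect_lt(sd(ev$strides$speed) / mean(ev$strides$speed), 0.1)
  # stance + swing = cycle by construction of stance_fraction
  expect_true(all(ev$strides$stance_fraction > 0 &
                    ev$strides$stance_fraction < 1, na.rm = TRUE))

  still <- pin_traj(1, 1, duration = 10, rate = 90)
  gs <- simulate_gait(still, p, seed = 3)
  evs <- detect_gait_cycles(gs[c("left", "right")])
  expect_equal(nrow(evs$strides), 0)
})

test_that("burst segmentation separates walking bouts by immobility", {
  # two bouts of cycles split by a 5 s standstill
  gait <- structure(list(heel_strikes = list(
    left = c(1.0, 2.0, 3.0, 10.0, 11.0),
    right = c(1.5, 2.5, 3.5, 10.5, 11.5))), class = "gait_events")
  tt <- seq(0, 15, by = 1 / 90)
  moving <- (tt >= 0.5 & tt <= 4) | (tt >= 9.5 & tt <= 12)
  traj <- data.frame(t = tt, x = 1 + cumsum(0.3 * moving / 90), y = 1,
                     z = 1.7, yaw = 0)
  f <- detect_bursts(gait, traj)
  expect_equal(unname(f["burst_count"]), 2)
  expect_equal(unname(f["cycles_per_burst_mean"]), 5)
  expect_gt(unname(f["immobility_total"]), 4)

  # uninterrupted walking: one burst, no immobility
  gait1 <- structure(list(heel_strikes = list(left = seq(1, 14, by = 0.7),
                                              right = seq(1.35, 14, by = 0.7))),
                     class = "gait_events")
  traj1 <- data.frame(t = tt, x = 1 + 0.3 * tt, y = 1, z = 1.7, yaw = 0)
  f1 <- detect_bursts(gait1, traj1)
  expect_equal(unname(f1["burst_count"]), 1)
  expect_equal(unname(f1["immobility_total"]), 0)

  # no cycles at all: zero bursts, immobility spans the session
  gait0 <- structure(list(heel_strikes = list(left = numeric(0),
                                              right = numeric(0))),
                     class = "gait_events")
  still <- pin_traj(1, 1, duration = 15, rate = 90)
  f0 <- detect_bursts(gait0, still)
  expect_equal(unname(f0["burst_count"]), 0)
  expect_equal(unname(f0["immobility_total"]), 15, tolerance = 0.1)
})

test_that("feature table assembly tags, deduplicates and reproduces", {
  co <- generate_cohort(4, coupling = 0.5, seed = 31)
  tab <- build_feature_table(co)
  expect_equal(nrow(tab), 4)
  info <- attr(tab, "feature_info")
  expect_true(all(info$family %in% c("position", "gait", "burst")))
  expect_true(all(info$scenario %in% c("er", "ea")))
  expect_gte(nrow(info), 55)
  # the nine headline features are present
  headline <- c("corner_dist_min_er", "vert_acc_rms_ea",
                "ratio_center_periphery_er", "time_narrow_ea", "focus_er",
                "stride_speed_cv_er", "head_scans_er", "time_board_ea",
                "max_y_ea")
  expect_true(all(headline %in% info$name))
  expect_identical(tab, build_feature_table(co))

  dup <- c(co, co[1])
  expect_error(build_feature_table(dup), "duplicate")

  # missing mocap: gait and burst features missing, position intact
  co2 <- co
  co2[[2]]$sessions$empty_room$foot_tracks <- NULL
  tab2 <- build_feature_table(co2)
  expect_true(is.na(tab2$stride_speed_cv_er[2]))
  expect_false(is.na(tab2$corner_dist_min_er[2]))
})

test_that("features are robust to halving the sampling rate", {
  p <- trait_profile(thigmotaxis_bias = 0.5, gait_speed_cv = 0.15)
  tr <- simulate_trajectory(p, er_geom, 90, 90, seed = 41)
  t45 <- resample_trajectory(tr, 45)
  f90 <- c(position_features_er(tr, er_geom), kinematics_features(tr))
  f45 <- c(position_features_er(t45, er_geom), kinematics_features(t45))
  for (nm in c("corner_dist_mean", "wall_dist_mean", "time_center",
               "speed_mean", "path_length")) {
    denom <- max(abs(f90[nm]), 1e-6)
    expect_lt(abs(f90[nm] - f45[nm]) / denom, 0.05)
  }
})

test_that("thigmotaxis bias monotonically shrinks center time", {
  means <- vapply(c(0.1, 0.5, 0.9), function(b) {
    p <- trait_profile(thigmotaxis_bias = b, center_avoidance = b)
    mean(vapply(1:6, function(s) {
      tr <- simulate_trajectory(p, er_geom, 90, 90, seed = 50 + s)
      unname(position_features_er(tr, er_geom)["time_center"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
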