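# Synthetic cohort generator: a latent vulnerability trait jointly drives
# exploratory locomotion (scenarios 1-2) and dark-maze cardiac physiology
# (scenario 3), so every downstream stage can be tested against ground truth.

#' Simulate a head-tracking trajectory
#'
#' Biased random-waypoint walk inside a scene. Waypoints are drawn from a
#' mixture of a wall-adjacent band (mixture weight = the profile's
#' thigmotaxis bias) and the room interior; interior waypoints falling in
#' the center zone are resampled with probability `center_avoidance`. On the
#' elevated alley the longitudinal reach shrinks with center avoidance
#' instead. Segment speeds are lognormal with coefficient of variation
#' `gait_speed_cv`; pauses between waypoints create immobility periods.
#' Yaw follows the heading of movement plus scripted square-pulse scan
#' excursions (amplitude 40 deg, duration 1 s) at a Poisson rate decreasing
#' in vulnerability; their onsets are returned as ground truth.
#'
#' @param profile a [trait_profile()].
#' @param geometry a [scene_geometry()].
#' @param duration recording length, s.
#' @param rate sampling rate, Hz (>= 10).
#' @param seed integer seed.
#' @param mean_speed mean locomotion speed, m/s; 0 gives a stationary
#'   recording at the start point.
#' @return data.frame with columns `t, x, y, z, yaw`; attributes
#'   `scan_times` (true scan onsets, s) and `rate`.
#' @export
simulate_trajectory <- function(profile, geometry, duration = 90, rate = 90,
                                seed = 1, mean_speed = 0.6) {
  if (duration <= 0) stopf("duration must be positive")
  if (rate < 10) stopf("rate must be >= 10 Hz")
  set.seed(seed)
  w <- geometry$room_width; L <- geometry$room_length
  start <- c(w / 2, 0.3)
  tt <- seq(0, duration, by = 1 / rate)

  if (mean_speed <= 0) {
    out <- data.frame(t = tt, x = start[1], y = start[2], z = 1.7, yaw = 90)
    attr(out, "scan_times") <- numeric(0)
    attr(out, "rate") <- rate
    return(out)
  }

  sdlog <- sqrt(log(1 + profile$gait_speed_cv^2))
  meanlog <- log(mean_speed) - sdlog^2 / 2
  y_reach <- geometry$board_length +
    (L - geometry$board_length) * (1 - 0.85 * profile$center_avoidance)

  # Build knots (time, x, y): dwell segments repeat the position, travel
  # segments move at the drawn speed; linear interpolation between knots.
  kt <- 0; kx <- start[1]; ky <- start[2]
  cur <- start; t_acc <- 0
  while (t_acc < duration + 0.5) {
    if (runif(1) < 0.35) {
      dwell <- min(rexp(1, 1 / 1.2), 5)
      t_acc <- t_acc + dwell
      kt <- c(kt, t_acc); kx <- c(kx, cur[1]); ky <- c(ky, cur[2])
    }
    if (geometry$kind == "alley") {
      cy <- min(max(cur[2] + runif(1, -1, 1) * 1.2, 0.15), y_reach)
      hw <- max(half_width_at(geometry, cy) - 0.1, 0.05)
      cand <- c(w / 2 + runif(1, -1, 1) * hw, cy)
    } else {
      cand <- cur
      for (k in 1:20) {
        ang <- runif(1, 0, 2 * pi)
        cand <- cur + runif(1, 0.6, 1.5) * c(cos(ang), sin(ang))
        cand[1] <- min(max(cand[1], 0.05), w - 0.05)
        cand[2] <- min(max(cand[2], 0.05), L - 0.05)
        if (runif(1) < profile$thigmotaxis_bias) {
          # project into the wall-adjacent band: set the distance to the
          # nearest wall to a draw from [0.05, 0.4]
          target <- runif(1, 0.05, 0.4)
          d <- c(cand[1], w - cand[1], cand[2], L - cand[2])
          side <- which.min(d)
          cand[c(1, 1, 2, 2)[side]] <- c(target, w - target, target, L - target)[side]
          break
        }
        if (in_center_zone(geometry, cand[1], cand[2]) &&
            runif(1) < profile$center_avoidance) next
        break
      }
    }
    sp <- rlnorm(1, meanlog, sdlog)
    seg <- sqrt(sum((cand - cur)^2))
    t_acc <- t_acc + seg / max(sp, 0.05)
    kt <- c(kt, t_acc); kx <- c(kx, cand[1]); ky <- c(ky, cand[2])
    cur <- cand
  }

  x <- approx(kt, kx, xout = tt, rule = 2, ties = "ordered")$y
  y <- approx(kt, ky, xout = tt, rule = 2, ties = "ordered")$y
  cl <- clip_to_geometry(geometry, x, y)
  x <- cl$x; y <- cl$y

  dt <- 1 / rate
  vx <- c(diff(x), 0) / dt
  vy <- c(diff(y), 0) / dt
  speed <- sqrt(vx^2 + vy^2)
  heading <- atan2(vy, vx) * 180 / pi
  moving <- speed > 0.05
  heading[!moving] <- NA
  if (is.na(heading[1])) heading[1] <- 90
  heading <- interp_flagged(heading, is.na(heading))
  # carry-forward semantics for stationary stretches
  last <- heading[1]
  for (i in seq_along(heading)) {
    if (moving[i]) last <- heading[i] else heading[i] <- last
  }

  yaw <- heading
  scan_rate <- 2 + 8 * plogis(-profile$vulnerability)  # scans per minute
  n_scan <- rpois(1, scan_rate * duration / 60)
  scan_times <- numeric(0)
  if (n_scan > 0) {
    walk_idx <- which(speed > 0.25 & tt < duration - 1.5)
    if (length(walk_idx)) {
      cand_t <- sort(tt[sample(walk_idx, min(n_scan, length(walk_idx)))])
      for (s0 in cand_t) {
        if (!length(scan_times) || s0 - tail(scan_times, 1) > 4) {
          scan_times <- c(scan_times, s0)
          sgn <- sample(c(-1, 1), 1)
          yaw[tt >= s0 & tt < s0 + 1] <- yaw[tt >= s0 & tt < s0 + 1] + sgn * 40
        }
      }
    }
  }

  z <- 1.7 + 0.015 * sin(2 * pi * 1.9 * tt) * (speed > 0.2)
  out <- data.frame(t = tt, x = x, y = y, z = z, yaw = yaw)
  attr(out, "scan_times") <- scan_times
  attr(out, "rate") <- rate
  out
}

#' Simulate an RR (interbeat) interval series
#'
#' Each NN interval is the profile's mean NN plus stationary AR(1) noise
#' (stationary SD = `nn_sd`) plus a respiratory sinus arrhythmia term
#' `rsa_amplitude * sin(2*pi*f_resp*t)` evaluated at the beat time. Beat
#' times are the cumulative sum of intervals, starting at 0.
#'
#' @param profile a [trait_profile()].
#' @param duration recording length, s (must exceed two mean beats).
#' @param seed integer seed.
#' @param ar_coef AR(1) coefficient of the beat-to-beat noise.
#' @return list with `beat_times` (s) and `nn` (ms, ground truth,
#'   `length(beat_times) - 1`).
#' @export
simulate_rr_series <- function(profile, duration = 90, seed = 1, ar_coef = 0.3) {
  if (profile$mean_nn <= 0) stopf("mean_nn must be positive")
  if (duration <= 2 * profile$mean_nn / 1000) stopf("duration too short for mean_nn")
  set.seed(seed)
  innov_sd <- profile$nn_sd * sqrt(1 - ar_coef^2)
  f <- profile$resp_rate / 60
  nmax <- ceiling(duration * 1000 / profile$mean_nn * 2) + 8
  beat_times <- numeric(nmax); nn <- numeric(nmax)
  t <- 0; ar <- if (profile$nn_sd > 0) rnorm(1, 0, profile$nn_sd) else 0
  nb <- 1L; beat_times[1] <- 0
  repeat {
    interval <- profile$mean_nn + ar +
      profile$rsa_amplitude * sin(2 * pi * f * t)
    interval <- max(interval, 250)  # physiological floor
    tn <- t + interval / 1000
    if (tn > duration + 1e-9) break
    nn[nb] <- interval
    nb <- nb + 1L
    beat_times[nb] <- tn
    t <- tn
    ar <- ar_coef * ar + if (innov_sd > 0) rnorm(1, 0, innov_sd) else 0
  }
  list(beat_times = beat_times[seq_len(nb)], nn = nn[seq_len(nb - 1L)])
}

ricker <- function(x, s) (1 - (x / s)^2) * exp(-x^2 / (2 * s^2))

#' Synthesize an ECG waveform from beat times
#'
#' Places a QRS-like Ricker wavelet (plus small P and T waves) at each beat
#' time and adds baseline wander and white noise scaled to the requested
#' signal-to-noise ratio. SNR is in dB relative to the RMS of the clean
#' waveform; `snr = Inf` gives a noiseless signal.
#'
#' @param beat_times beat times, s.
#' @param fs sampling rate, Hz (>= 250).
#' @param snr signal-to-noise ratio in dB (`Inf` = clean).
#' @param duration length of the waveform, s (default: last beat + 0.4 s).
#' @param seed integer seed.
#' @return list with `ecg` (an [ecg_signal()]), `beat_index` (true R sample
#'   indices) and `beat_times`.
#' @export
synthesize_ecg <- function(beat_times, fs = 500, snr = Inf, duration = NULL,
                           seed = 1) {
  if (!length(beat_times)) stopf("beat_times must be non-empty")
  if (fs < 250) stopf("fs must be >= 250 Hz")
  duration <- duration %||% (max(beat_times) + 0.4)
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  clean <- numeric(n)
  add_wave <- function(center, amp, width, shape) {
    i0 <- max(1, floor((center - 4 * width) * fs) + 1)
    i1 <- min(n, ceiling((center + 4 * width) * fs) + 1)
    if (i0 > i1) return()
    idx <- i0:i1
    dtc <- tt[idx] - center
    clean[idx] <<- clean[idx] + amp *
      if (shape == "ricker") ricker(dtc, width) else exp(-dtc^2 / (2 * width^2))
  }
  for (b in beat_times) {
    add_wave(b, 1.0, 0.012, "ricker")       # QRS
    add_wave(b - 0.18, 0.10, 0.035, "gauss")  # P
    add_wave(b + 0.28, 0.20, 0.060, "gauss")  # T
  }
  set.seed(seed)
  if (is.finite(snr)) {
    nsd <- sqrt(mean(clean^2)) * 10^(-snr / 20)
    wander <- 1.5 * nsd * sin(2 * pi * 0.28 * tt + runif(1, 0, 2 * pi))
    samples <- clean + rnorm(n, 0, nsd) + wander
  } else {
    samples <- clean
  }
  beat_index <- pmin(pmax(round(beat_times * fs) + 1, 1), n)
  list(ecg = ecg_signal(samples, fs), beat_index = beat_index,
       beat_times = beat_times)
}

#' Simulate a respiration waveform
#'
#' @param resp_rate true rate, breaths/min (> 0).
#' @param duration length, s.
#' @param fs sampling rate, Hz (>= 25).
#' @param noise_sd white-noise SD (signal amplitude is 1).
#' @param seed integer seed.
#' @return a [resp_signal()] with attribute `true_rate`.
#' @export
simulate_respiration <- function(resp_rate, duration = 90, fs = 100,
                                 noise_sd = 0, seed = 1) {
  if (resp_rate <= 0) stopf("resp_rate must be positive")
  if (fs < 25) stopf("fs must be >= 25 Hz")
  set.seed(seed)
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * resp_rate / 60 * tt)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  out <- resp_signal(x, fs)
  attr(out, "true_rate") <- resp_rate
  out
}

#' Simulate lower-body gait from a head trajectory
#'
#' Places alternating left/right heel strikes every half stride length of
#' walking distance (head horizontal speed above the stepping threshold).
#' Each foot holds its strike position during stance and follows an arc
#' (5 cm lift) to the next strike during swing. True heel-strike times are
#' returned per foot.
#'
#' @param head_track data.frame `t, x, y` (output of
#'   [simulate_trajectory()]).
#' @param profile a [trait_profile()] (reserved for gait styling).
#' @param seed integer seed.
#' @param rate mocap sampling rate, Hz.
#' @param stride_length stride length, m (ipsilateral strike-to-strike).
#' @param step_threshold minimum head speed for stepping, m/s.
#' @return list with `left`, `right` (data.frames `t, x, y, z`) and
#'   `heel_strikes` (list of true strike times per foot).
#' @export
simulate_gait <- function(head_track, profile, seed = 1, rate = 60,
                          stride_length = 0.7, step_threshold = 0.2) {
  if (!nrow(head_track)) stopf("head_track must be non-empty")
  set.seed(seed)
  t <- head_track$t
  dt <- median(diff(t))
  vx <- c(diff(head_track$x), 0) / dt
  vy <- c(diff(head_track$y), 0) / dt
  speed <- moving_average(sqrt(vx^2 + vy^2), max(3, round(0.5 / dt)))
  walking <- speed > step_threshold
  dinc <- sqrt(c(diff(head_track$x), 0)^2 + c(diff(head_track$y), 0)^2)
  cumdist <- cumsum(dinc * walking)

  half <- stride_length / 2
  duration <- max(t)
  tm <- seq(0, duration, by = 1 / rate)
  base_off <- 0.09
  heading <- atan2(vy, vx)

  mk_track <- function(strikes, side_sign) {
    if (!length(strikes$t)) {
      return(data.frame(t = tm, x = head_track$x[1] + side_sign * base_off,
                        y = head_track$y[1], z = 0))
    }
    ktime <- numeric(0); kx <- numeric(0); ky <- numeric(0); kz <- numeric(0)
    push <- function(ti, xi, yi, zi) {
      if (length(ktime) && ti <= tail(ktime, 1)) ti <- tail(ktime, 1) + 1e-6
      ktime <<- c(ktime, ti); kx <<- c(kx, xi); ky <<- c(ky, yi); kz <<- c(kz, zi)
    }
    # feet start under the head and swing into the first strike
    x0 <- head_track$x[1] + side_sign * base_off
    y0 <- head_track$y[1]
    push(-0.01, x0, y0, 0)
    if (strikes$t[1] > 0.05) {
      sw0 <- min(0.3, strikes$t[1] / 2)
      push(strikes$t[1] - sw0, x0, y0, 0)
      push(strikes$t[1] - sw0 / 2, (x0 + strikes$x[1]) / 2,
           (y0 + strikes$y[1]) / 2, 0.05)
    }
    push(strikes$t[1], strikes$x[1], strikes$y[1], 0)
    ns <- length(strikes$t)
    for (i in seq_len(ns - 1)) {
      d <- strikes$t[i + 1] - strikes$t[i]
      swing <- min(0.4 * d, 0.6)
      t_off <- strikes$t[i + 1] - swing
      push(t_off, strikes$x[i], strikes$y[i], 0)            # toe-off
      push(t_off + swing / 2,
           (strikes$x[i] + strikes$x[i + 1]) / 2,
           (strikes$y[i] + strikes$y[i + 1]) / 2, 0.05)      # mid-swing apex
      push(strikes$t[i + 1], strikes$x[i + 1], strikes$y[i + 1], 0)
    }
    push(duration + 1, strikes$x[ns], strikes$y[ns], 0)
    data.frame(t = tm,
               x = approx(ktime, kx, xout = tm, rule = 2)$y,
               y = approx(ktime, ky, xout = tm, rule = 2)$y,
               z = approx(ktime, kz, xout = tm, rule = 2)$y)
  }

  if (max(cumdist) < half) {
    empty <- list(t = numeric(0), x = numeric(0), y = numeric(0))
    left <- mk_track(empty, -1); right <- mk_track(empty, 1)
    return(list(left = left, right = right,
                heel_strikes = list(left = numeric(0), right = numeric(0))))
  }

  strike_d <- seq(half, max(cumdist), by = half)
  ok <- !duplicated(cumdist)
  strike_t <- approx(cumdist[ok], t[ok], xout = strike_d, ties = "ordered")$y
  keep <- !is.na(strike_t)
  strike_t <- strike_t[keep]
  sx <- approx(t, head_track$x, xout = strike_t)$y
  sy <- approx(t, head_track$y, xout = strike_t)$y
  hd <- approx(t, heading, xout = strike_t, rule = 2)$y
  first_left <- runif(1) < 0.5
  is_left <- rep(c(first_left, !first_left), length.out = length(strike_t))
  offs <- ifelse(is_left, -base_off, base_off)
  sx <- sx + offs * -sin(hd)
  sy <- sy + offs * cos(hd)

  strikes_left <- list(t = strike_t[is_left], x = sx[is_left], y = sy[is_left])
  strikes_right <- list(t = strike_t[!is_left], x = sx[!is_left], y = sy[!is_left])
  list(left = mk_track(strikes_left, -1),
       right = mk_track(strikes_right, 1),
       heel_strikes = list(left = strikes_left$t, right = strikes_right$t))
}

# Deterministic trait maps: latent vulnerability -> behavioral and
# (scenario-3, coupling-scaled) physiological parameters.
trait_maps <- function(v, coupling, mean_nn_base, nn_sd_base, rsa_base) {
  list(thigmotaxis_bias = plogis(1.2 * v),
       center_avoidance = plogis(1.0 * v),
       gait_speed_cv = 0.05 + 0.30 * plogis(-v),
       mean_nn3 = pmax(mean_nn_base - 120 * tanh(coupling * v), 450),
       nn_sd3 = nn_sd_base * exp(-0.7 * tanh(coupling * v)),
       rsa3 = rsa_base * exp(-0.7 * tanh(coupling * v)))
}

#' One subject-by-scenario session recording
#'
#' @param subject_id character id.
#' @param scenario_id one of `empty_room`, `elevated_alley`, `dark_maze`.
#' @param head_track data.frame `t, x, y, z, yaw`.
#' @param foot_tracks list `left`/`right` data.frames (or NULL).
#' @param ecg an [ecg_signal()] (or NULL).
#' @param respiration a [resp_signal()] (or NULL).
#' @param duration s.
#' @param truth list of generator ground truth (beat times, NN list, true
#'   respiration rate, heel strikes, scan onsets).
#' @return object of class `session_recording`.
#' @export
session_recording <- function(subject_id, scenario_id, head_track,
                              foot_tracks = NULL, ecg = NULL,
                              respiration = NULL, duration = 90,
                              truth = list()) {
  if (is.unsorted(head_track$t, strictly = TRUE)) stopf("timestamps must be strictly increasing")
  structure(list(subject_id = subject_id, scenario_id = scenario_id,
                 head_track = head_track, foot_tracks = foot_tracks,
                 ecg = ecg, respiration = respiration,
                 duration = duration, truth = truth),
            class = "session_recording")
}

#' Generate a synthetic cohort
#'
#' Draws a standard-normal latent vulnerability per subject and maps it
#' monotonically to exploration parameters (wall hugging and center
#' avoidance increase with vulnerability, speed variability decreases) and
#' to dark-maze (scenario 3) physiology: mean NN, beat-to-beat SD and RSA
#' amplitude all decrease with `coupling * vulnerability` (vagal
#' withdrawal). Trait anxiety (STAI-T) is drawn uniformly over 20-60,
#' independent of vulnerability. Each subject gets three 90-s session
#' recordings with all channels and full ground truth.
#'
#' @param n number of subjects (>= 2).
#' @param coupling effect size of the vulnerability-to-physiology link
#'   (>= 0; 0 decouples scenario-3 physiology from behavior).
#' @param seed integer master seed.
#' @param duration session length, s.
#' @param rate_track,rate_mocap,rate_ecg,rate_resp channel sampling rates, Hz.
#' @param ecg_snr ECG signal-to-noise ratio, dB.
#' @return object of class `cohort`: list of subjects, each with
#'   `subject_id`, `vulnerability`, `stai_t`, `profile` and `sessions`
#'   (named list of [session_recording()]s).
#' @export
generate_cohort <- function(n, coupling = 1, seed = 1, duration = 90,
                            rate_track = 90, rate_mocap = 60,
                            rate_ecg = 500, rate_resp = 100, ecg_snr = 15) {
  if (n < 2) stopf("n must be >= 2")
  if (coupling < 0) stopf("coupling must be >= 0")
  set.seed(seed)
  v <- rnorm(n)
  stai <- runif(n, 20, 60)
  mean_nn_base <- 900 + rnorm(n, 0, 40)
  nn_sd_base <- pmax(45 + rnorm(n, 0, 6), 10)
  rsa_base <- pmax(28 + rnorm(n, 0, 4), 5)
  resp_base <- runif(n, 12, 18)
  maps <- trait_maps(v, coupling, mean_nn_base, nn_sd_base, rsa_base)

  scenarios <- c("empty_room", "elevated_alley", "dark_maze")
  geoms <- lapply(scenarios, scene_geometry)
  names(geoms) <- scenarios

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    resp_i <- pmin(pmax(resp_base[i] + runif(3, -1, 1), 10.5), 25)
    sessions <- vector("list", 3)
    names(sessions) <- scenarios
    for (s in seq_along(scenarios)) {
      sc <- scenarios[s]
      dark <- sc == "dark_maze"
      prof <- trait_profile(
        vulnerability = v[i],
        thigmotaxis_bias = maps$thigmotaxis_bias[i],
        center_avoidance = maps$center_avoidance[i],
        gait_speed_cv = maps$gait_speed_cv[i],
        mean_nn = if (dark) maps$mean_nn3[i] else mean_nn_base[i],
        nn_sd = if (dark) maps$nn_sd3[i] else nn_sd_base[i],
        rsa_amplitude = if (dark) maps$rsa3[i] else rsa_base[i],
        resp_rate = resp_i[s])
      s_tag <- paste(sid, sc)
      traj <- simulate_trajectory(prof, geoms[[sc]], duration, rate_track,
                                  seed = derive_seed(seed, paste(s_tag, "traj")))
      gait <- simulate_gait(traj, prof, rate = rate_mocap,
                            seed = derive_seed(seed, paste(s_tag, "gait")))
      rr <- simulate_rr_series(prof, duration,
                               seed = derive_seed(seed, paste(s_tag, "rr")))
      ecg <- synthesize_ecg(rr$beat_times, rate_ecg, ecg_snr, duration,
                            seed = derive_seed(seed, paste(s_tag, "ecg")))
      resp <- simulate_respiration(prof$resp_rate, duration, rate_resp,
                                   noise_sd = 0.05,
                                   seed = derive_seed(seed, paste(s_tag, "resp")))
      sessions[[sc]] <- session_recording(
        sid, sc, traj, foot_tracks = gait[c("left", "right")],
        ecg = ecg$ecg, respiration = resp, duration = duration,
        truth = list(beat_times = rr$beat_times, nn = rr$nn,
                     beat_index = ecg$beat_index,
                     resp_rate = prof$resp_rate,
                     heel_strikes = gait$heel_strikes,
                     scan_times = attr(traj, "scan_times"),
                     profile = prof))
    }
    subjects[[i]] <- list(subject_id = sid, vulnerability = v[i],
                          stai_t = stai[i],
                          profile = trait_profile(
                            vulnerability = v[i],
                            thigmotaxis_bias = maps$thigmotaxis_bias[i],
                            center_avoidance = maps$center_avoidance[i],
                            gait_speed_cv = maps$gait_speed_cv[i],
                            mean_nn = mean_nn_base[i],
                            nn_sd = nn_sd_base[i],
                            rsa_amplitude = rsa_base[i],
                            resp_rate = resp_base[i]),
                          sessions = sessions)
  }
  structure(subjects, class = "cohort", n = n, coupling = coupling, seed = seed)
}

#' Ground truth table for a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with vulnerability, STAI-T and the true scenario-3
#'   NN-derived metrics (RMSSD, SDNN, mean NN) computed directly from the
#'   generator's latent NN list.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    nn <- s$sessions$dark_maze$truth$nn
    data.frame(subject_id = s$subject_id,
               vulnerability = s$vulnerability,
               stai_t = s$stai_t,
               rmssd3_true = sqrt(mean(diff(nn)^2)),
               sdnn3_true = sd(nn),
               mean_nn3_true = mean(nn))
  }))
}
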