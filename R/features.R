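# Locomotor featurization: position/trajectory, gait and movement-burst
# feature families from head tracking and lower-body motion capture.

#' Resample a trajectory to a uniform rate
#'
#' Linear interpolation of x, y, z and (unwrapped) yaw onto a uniform time
#' grid; all feature extractors assume a uniform dt.
#'
#' @param traj data.frame `t, x, y` (optionally `z`, `yaw`).
#' @param rate target rate, Hz; default keeps the median native rate.
#' @return data.frame on a uniform grid.
#' @export
resample_trajectory <- function(traj, rate = NULL) {
  if (nrow(traj) < 2) stopf("trajectory needs at least 2 samples")
  if (is.unsorted(traj$t)) stopf("trajectory timestamps must be monotone")
  rate <- rate %||% (1 / median(diff(traj$t)))
  tt <- seq(min(traj$t), max(traj$t), by = 1 / rate)
  out <- data.frame(t = tt,
                    x = approx(traj$t, traj$x, tt, rule = 2)$y,
                    y = approx(traj$t, traj$y, tt, rule = 2)$y)
  if (!is.null(traj$z)) out$z <- approx(traj$t, traj$z, tt, rule = 2)$y
  if (!is.null(traj$yaw)) {
    uw <- unwrap_deg(traj$yaw)
    out$yaw <- approx(traj$t, uw, tt, rule = 2)$y
  }
  out
}

unwrap_deg <- function(a) {
  d <- c(0, diff(a))
  d <- d - 360 * round(d / 360)
  a[1] + cumsum(d)
}

check_in_room <- function(traj, geometry, tol = 1e-6) {
  if (any(traj$x < -tol | traj$x > geometry$room_width + tol |
          traj$y < -tol | traj$y > geometry$room_length + tol)) {
    stopf("trajectory leaves the room bounds")
  }
}

feat <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

#' Empty-room position features
#'
#' Distances to the corners and walls, center-zone occupancy and the
#' (guarded) center/periphery time ratio, occupancy-grid coverage and the
#' latency to first center entry. The center/periphery ratio is capped at
#' `duration / dt` when the subject never visits the periphery (flagged via
#' attribute `capped`); the latency is the session duration when the center
#' is never entered.
#'
#' @param traj uniform trajectory data.frame (`t, x, y`).
#' @param geometry the empty-room [scene_geometry()].
#' @return named numeric feature vector.
#' @export
position_features_er <- function(traj, geometry) {
  check_in_room(traj, geometry)
  dt <- median(diff(traj$t))
  dur <- max(traj$t) - min(traj$t)
  cd <- corner_distances(traj, geometry)
  wd <- wall_distance(geometry, traj$x, traj$y)
  inc <- in_center_zone(geometry, traj$x, traj$y)
  # occupancy times as sample fractions of the duration, so zone times sum
  # exactly to the session length
  t_center <- mean(inc) * dur
  t_peri <- mean(!inc) * dur
  ratio <- if (t_peri > 0) t_center / t_peri else dur / dt
  first_in <- which(inc)[1]
  latency <- if (is.na(first_in)) dur else traj$t[first_in] - traj$t[1]
  out <- feat(corner_dist_min = min(cd), corner_dist_mean = mean(cd),
              wall_dist_min = min(wd), wall_dist_mean = mean(wd),
              time_center = t_center, time_periphery = t_peri,
              ratio_center_periphery = ratio,
              coverage = grid_coverage(traj, geometry),
              latency_center = latency)
  attr(out, "capped") <- t_peri == 0
  out
}

corner_distances <- function(traj, geometry) {
  cp <- geometry$corner_points
  d <- matrix(Inf, nrow(traj), nrow(cp))
  for (k in seq_len(nrow(cp))) {
    d[, k] <- sqrt((traj$x - cp[k, 1])^2 + (traj$y - cp[k, 2])^2)
  }
  apply(d, 1, min)
}

grid_coverage <- function(traj, geometry, cell = 0.25) {
  nx <- ceiling(geometry$room_width / cell)
  ny <- ceiling(geometry$room_length / cell)
  ix <- pmin(pmax(floor(traj$x / cell), 0), nx - 1)
  iy <- pmin(pmax(floor(traj$y / cell), 0), ny - 1)
  length(unique(ix + nx * iy)) / (nx * ny)
}

#' Elevated-alley position features
#'
#' Per-patch dwell times, first-crossing time of each patch threshold, time
#' on the starting board, time on the narrowest ledge, maximal longitudinal
#' distance reached and the number of retreats (returns toward the board by
#' more than 0.2 m from a running maximum). Crossing times are `NA` when a
#' threshold is never reached.
#'
#' @param traj uniform trajectory data.frame.
#' @param geometry the elevated-alley [scene_geometry()].
#' @return named numeric feature vector.
#' @export
position_features_ea <- function(traj, geometry) {
  check_in_room(traj, geometry)
  dur0 <- max(traj$t) - min(traj$t)
  y <- traj$y
  edges <- cumsum(geometry$alley_patches$length)
  npatch <- nrow(geometry$alley_patches)
  patch_idx <- pmin(findInterval(y, c(0, edges), rightmost.closed = TRUE), npatch)
  patch_idx[patch_idx < 1] <- 1
  dwell <- vapply(seq_len(npatch),
                  function(k) mean(patch_idx == k) * dur0, numeric(1))
  names(dwell) <- paste0("time_patch", seq_len(npatch))
  thr <- head(edges, -1)
  dur <- max(traj$t) - min(traj$t)
  cross <- vapply(thr, function(th) {
    i <- which(y >= th)[1]
    if (is.na(i)) dur else traj$t[i] - traj$t[1]  # right-censored at session end
  }, numeric(1))
  names(cross) <- paste0("cross_time", seq_along(thr))
  runmax <- cummax(y)
  retreat <- runmax - y >= 0.2
  n_retreats <- sum(diff(c(FALSE, retreat)) == 1)
  c(dwell, cross,
    feat(time_board = mean(y < geometry$board_length) * dur0,
         time_narrow = dwell[[npatch]],
         max_y = max(y),
         n_retreats = n_retreats))
}

#' Kinematic features from a trajectory
#'
#' Positions are smoothed with a 0.5-s moving average before central
#' differencing. Emits horizontal speed mean/SD/max, RMS horizontal and
#' vertical acceleration and total path length.
#'
#' @param traj uniform trajectory data.frame (`t, x, y`, optionally `z`).
#' @param smooth_window smoothing window, s.
#' @return named numeric feature vector.
#' @export
kinematics_features <- function(traj, smooth_window = 0.5) {
  if (nrow(traj) < 3) stopf("kinematics need at least 3 samples")
  dt <- median(diff(traj$t))
  k <- max(1, round(smooth_window / dt))
  xs <- moving_average(traj$x, k, pad_mode = "odd")
  ys <- moving_average(traj$y, k, pad_mode = "odd")
  zs <- if (!is.null(traj$z)) moving_average(traj$z, k, pad_mode = "odd") else
    rep(0, nrow(traj))
  cd <- function(v) c(v[2] - v[1], (v[-(1:2)] - v[seq_len(length(v) - 2)]) / 2,
                      v[length(v)] - v[length(v) - 1]) / dt
  vx <- cd(xs); vy <- cd(ys); vz <- cd(zs)
  ax <- cd(vx); ay <- cd(vy); az <- cd(vz)
  sp <- sqrt(vx^2 + vy^2)
  feat(speed_mean = mean(sp), speed_sd = sd(sp), speed_max = max(sp),
       acc_rms = sqrt(mean(ax^2 + ay^2)),
       vert_acc_rms = sqrt(mean(az^2)),
       path_length = sum(sqrt(diff(xs)^2 + diff(ys)^2)))
}

#' Trajectory shape features (empty room)
#'
#' Focus is `1 - H(p) / log(K)` where `p` is the dwell-time distribution
#' over visited 0.25-m grid cells and `K` the number of visited cells: 1
#' when all time is spent in one cell, near 0 for uniform spread.
#' Concentric is the fraction of path length whose movement direction lies
#' within 45 degrees of the tangent to the circle through the current point
#' centered at the room center.
#'
#' @param traj uniform trajectory data.frame.
#' @param geometry the room [scene_geometry()].
#' @param cell occupancy grid cell size, m.
#' @return named numeric feature vector (`focus`, `concentric`).
#' @export
trajectory_shape_features <- function(traj, geometry, cell = 0.25) {
  if (nrow(traj) < 3) stopf("shape features need at least 3 samples")
  nx <- ceiling(geometry$room_width / cell)
  ix <- pmin(pmax(floor(traj$x / cell), 0), nx - 1)
  iy <- pmax(floor(traj$y / cell), 0)
  counts <- table(ix + nx * iy)
  p <- as.numeric(counts) / sum(counts)
  K <- length(p)
  focus <- if (K == 1) 1 else 1 - (-sum(p * log(p))) / log(K)

  cx <- geometry$room_width / 2; cy <- geometry$room_length / 2
  dx <- diff(traj$x); dy <- diff(traj$y)
  seg <- sqrt(dx^2 + dy^2)
  mov <- seg > 1e-9
  rx <- traj$x[-nrow(traj)] - cx; ry <- traj$y[-nrow(traj)] - cy
  rn <- sqrt(rx^2 + ry^2)
  ok <- mov & rn > 1e-9
  # |cos(angle to radial)| <= cos(45 deg) <=> within 45 deg of the tangent
  cosr <- abs(dx[ok] * rx[ok] + dy[ok] * ry[ok]) / (seg[ok] * rn[ok])
  concentric <- if (any(ok)) sum(seg[ok][cosr <= cos(pi / 4) + 1e-12]) / sum(seg[ok]) else 0
  feat(focus = focus, concentric = concentric)
}

#' Count head scans while walking
#'
#' A scan is an excursion of yaw away from the instantaneous movement
#' heading exceeding 30 degrees that returns below the threshold within
#' 3 s; only excursions starting while walking (horizontal speed above
#' 0.2 m/s) are counted.
#'
#' @param traj uniform trajectory data.frame with `yaw` (deg).
#' @param yaw_threshold excursion threshold, deg.
#' @param max_return maximal excursion duration, s.
#' @param walk_speed walking speed threshold, m/s.
#' @return named numeric feature vector (`head_scans`,
#'   `head_scans_per_min_walking`).
#' @export
head_scan_count <- function(traj, yaw_threshold = 30, max_return = 3,
                            walk_speed = 0.2) {
  if (is.null(traj$yaw)) stopf("trajectory has no yaw channel")
  dt <- median(diff(traj$t))
  n <- nrow(traj)
  vx <- c(diff(traj$x), 0) / dt
  vy <- c(diff(traj$y), 0) / dt
  speed <- sqrt(vx^2 + vy^2)
  heading <- atan2(vy, vx) * 180 / pi
  moving <- speed > 0.05
  last <- if (moving[1]) heading[1] else 90
  for (i in seq_len(n)) {
    if (moving[i]) last <- heading[i] else heading[i] <- last
  }
  dev <- abs(ang_diff(traj$yaw, heading))
  over <- dev > yaw_threshold
  count <- 0L
  i <- 2L
  while (i <= n) {
    if (over[i] && !over[i - 1]) {
      j <- i
      while (j <= n && over[j]) j <- j + 1L
      returned <- j <= n
      dur <- (j - i) * dt
      if (returned && dur <= max_return && speed[i] > walk_speed) count <- count + 1L
      i <- j
    }
    i <- i + 1L
  }
  walk_min <- sum(speed > walk_speed) * dt / 60
  feat(head_scans = count,
       head_scans_per_min_walking = if (walk_min > 0) count / walk_min else 0)
}

#' Detect gait cycles from foot tracks
#'
#' Stance onset (heel strike) is the start of a period with foot speed
#' below 0.15 m/s sustained for at least 0.1 s while the foot height is in
#' its lowest quartile; toe-off is the speed rising back above threshold.
#' Strides are built from consecutive ipsilateral strikes.
#'
#' @param foot_tracks list with `left` and `right` data.frames
#'   (`t, x, y, z`).
#' @param speed_threshold stance speed threshold, m/s.
#' @param min_stance minimal stance duration, s.
#' @return object of class `gait_events`: `heel_strikes`, `toe_offs` (per
#'   foot) and a `strides` data.frame (`foot, start, end, length, speed,
#'   stance_fraction`).
#' @export
detect_gait_cycles <- function(foot_tracks, speed_threshold = 0.15,
                               min_stance = 0.1) {
  if (is.null(foot_tracks$left) || is.null(foot_tracks$right)) {
    stopf("both feet must be present")
  }
  if (max(foot_tracks$left$t) - min(foot_tracks$left$t) < 2) {
    stopf("foot tracks must cover at least 2 s")
  }
  one_foot <- function(ft) {
    dt <- median(diff(ft$t))
    vx <- c(diff(ft$x), 0) / dt
    vy <- c(diff(ft$y), 0) / dt
    sp <- moving_average(sqrt(vx^2 + vy^2), max(3, round(0.08 / dt)))
    low <- sp < speed_threshold
    zq <- quantile(ft$z, 0.25)
    runs <- rle(low)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hs <- numeric(0); to <- numeric(0)
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      if ((ends[k] - starts[k] + 1) * dt < min_stance) next
      idx <- starts[k]:ends[k]
      if (median(ft$z[idx]) > zq + 0.02) next
      hs <- c(hs, ft$t[starts[k]])
      to <- c(to, ft$t[min(ends[k] + 1, nrow(ft))])
    }
    list(hs = hs, to = to, ft = ft)
  }
  L <- one_foot(foot_tracks$left)
  R <- one_foot(foot_tracks$right)
  strides <- list()
  for (side in c("left", "right")) {
    f <- if (side == "left") L else R
    if (length(f$hs) < 2) next
    for (k in seq_len(length(f$hs) - 1)) {
      s0 <- f$hs[k]; s1 <- f$hs[k + 1]
      p0 <- c(approx(f$ft$t, f$ft$x, s0)$y, approx(f$ft$t, f$ft$y, s0)$y)
      p1 <- c(approx(f$ft$t, f$ft$x, s1)$y, approx(f$ft$t, f$ft$y, s1)$y)
      len <- sqrt(sum((p1 - p0)^2))
      tok <- f$to[f$to > s0 & f$to <= s1]
      stance <- if (length(tok)) (tok[1] - s0) / (s1 - s0) else NA_real_
      strides[[length(strides) + 1]] <-
        data.frame(foot = side, start = s0, end = s1, length = len,
                   speed = len / (s1 - s0), stance_fraction = stance)
    }
  }
  strides <- if (length(strides)) do.call(rbind, strides) else
    data.frame(foot = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0), speed = numeric(0),
               stance_fraction = numeric(0))
  structure(list(heel_strikes = list(left = L$hs, right = R$hs),
                 toe_offs = list(left = L$to, right = R$to),
                 strides = strides), class = "gait_events")
}

# Scalar gait features from detected cycles.
gait_features <- function(events, duration) {
  st <- events$strides
  if (!nrow(st)) {
    return(feat(stride_count = 0, stride_speed_mean = NA, stride_speed_sd = NA,
                stride_speed_cv = NA, stride_length_mean = NA,
                stride_length_sd = NA, stride_duration_mean = NA,
                stance_fraction_mean = NA, cadence = 0))
  }
  dur <- st$end - st$start
  feat(stride_count = nrow(st),
       stride_speed_mean = mean(st$speed), stride_speed_sd = sd(st$speed),
       stride_speed_cv = sd(st$speed) / mean(st$speed),
       stride_length_mean = mean(st$length), stride_length_sd = sd(st$length),
       stride_duration_mean = mean(dur),
       stance_fraction_mean = mean(st$stance_fraction, na.rm = TRUE),
       cadence = nrow(st) / duration * 60)
}

#' Movement bursts and immobility
#'
#' A burst is a maximal run of gait cycles (heel strikes, both feet pooled)
#' whose inter-cycle gaps stay below 1.5 s; immobility is horizontal head
#' speed below 0.1 m/s sustained for at least 2 s.
#'
#' @param gait a [detect_gait_cycles()] result.
#' @param traj the time-aligned head trajectory.
#' @param gap_threshold maximal within-burst inter-cycle gap, s.
#' @param immobility_speed immobility speed threshold, m/s.
#' @param immobility_min minimal immobility duration, s.
#' @return named numeric feature vector.
#' @export
detect_bursts <- function(gait, traj, gap_threshold = 1.5,
                          immobility_speed = 0.1, immobility_min = 2) {
  cycles <- sort(c(gait$heel_strikes$left, gait$heel_strikes$right))
  dur <- max(traj$t) - min(traj$t)
  dt <- median(diff(traj$t))
  vx <- c(diff(traj$x), 0) / dt
  vy <- c(diff(traj$y), 0) / dt
  sp <- moving_average(sqrt(vx^2 + vy^2), max(3, round(0.5 / dt)))
  slow <- sp < immobility_speed
  runs <- rle(slow)
  lens <- runs$lengths * dt
  imm <- lens[runs$values & lens >= immobility_min]
  imm_total <- sum(imm)
  imm_longest <- if (length(imm)) max(imm) else 0

  if (!length(cycles)) {
    return(feat(burst_count = 0, burst_duration_mean = NA,
                burst_duration_max = NA, cycles_per_burst_mean = NA,
                immobility_total = imm_total,
                immobility_longest = imm_longest))
  }
  brk <- which(diff(cycles) >= gap_threshold)
  starts <- c(1, brk + 1)
  ends <- c(brk, length(cycles))
  bdur <- cycles[ends] - cycles[starts]
  feat(burst_count = length(starts),
       burst_duration_mean = mean(bdur), burst_duration_max = max(bdur),
       cycles_per_burst_mean = mean(ends - starts + 1),
       immobility_total = imm_total, immobility_longest = imm_longest)
}

# Full feature vector for one session; tags carried by build_feature_table.
session_features <- function(session, geometry = NULL) {
  sc <- session$scenario_id
  geometry <- geometry %||% scene_geometry(sc)
  traj <- resample_trajectory(session$head_track)
  dur <- max(traj$t) - min(traj$t)
  pos <- c(kinematics_features(traj),
           if (sc == "empty_room") c(position_features_er(traj, geometry),
                                     trajectory_shape_features(traj, geometry),
                                     head_scan_count(traj))
           else if (sc == "elevated_alley") position_features_ea(traj, geometry))
  gait <- NULL; burst <- NULL
  if (!is.null(session$foot_tracks)) {
    ev <- detect_gait_cycles(session$foot_tracks)
    gait <- gait_features(ev, dur)
    burst <- detect_bursts(ev, traj)
  } else {
    gait <- gait_features(structure(list(strides = data.frame()),
                                    class = "gait_events"), dur) * NA
    burst <- feat(burst_count = NA, burst_duration_mean = NA,
                  burst_duration_max = NA, cycles_per_burst_mean = NA,
                  immobility_total = NA, immobility_longest = NA)
  }
  list(position = pos, gait = gait, burst = burst)
}

#' Build the subject-by-feature table
#'
#' Extracts all position, gait and movement-burst features from scenarios 1
#' (empty room) and 2 (elevated alley) for every subject. Feature names are
#' suffixed `_er` / `_ea`; each column carries a family tag (position,
#' gait, burst) in the `feature_info` attribute. Subjects whose row exceeds
#' the missingness threshold are excluded with a message.
#'
#' @param cohort a [generate_cohort()] result or list of subjects with
#'   `subject_id` and `sessions$empty_room` / `sessions$elevated_alley`.
#' @param max_missing maximal tolerated fraction of missing features.
#' @return object of class `feature_table`: data.frame with `subject_id`
#'   plus feature columns; attribute `feature_info` is a data.frame
#'   (`name, family, scenario`).
#' @export
build_feature_table <- function(cohort, max_missing = 0.5) {
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject ids")
  rows <- lapply(cohort, function(s) {
    out <- list()
    for (sc in c("empty_room", "elevated_alley")) {
      ses <- s$sessions[[sc]]
      if (is.null(ses)) stopf("subject %s is missing scenario %s", s$subject_id, sc)
      sf <- session_features(ses)
      sfx <- if (sc == "empty_room") "_er" else "_ea"
      for (fam in names(sf)) {
        v <- sf[[fam]]
        names(v) <- paste0(names(v), sfx)
        out[[length(out) + 1]] <- data.frame(name = names(v), value = as.numeric(v),
                                             family = fam,
                                             scenario = sub("_", "", sfx))
      }
    }
    do.call(rbind, out)
  })
  info <- rows[[1]][, c("name", "family", "scenario")]
  mat <- do.call(rbind, lapply(rows, function(r) {
    stopifnot(identical(r$name, info$name))
    r$value
  }))
  colnames(mat) <- info$name
  frac_missing <- rowMeans(is.na(mat))
  keep <- frac_missing <= max_missing
  if (!all(keep)) {
    message(sprintf("excluding %d subject(s) exceeding %.0f%% missing features: %s",
                    sum(!keep), 100 * max_missing,
                    paste(ids[!keep], collapse = ", ")))
  }
  tab <- data.frame(subject_id = ids[keep], mat[keep, , drop = FALSE],
                    check.names = FALSE)
  structure(tab, feature_info = info, class = c("feature_table", "data.frame"))
}

feature_info <- function(table) attr(table, "feature_info")

feature_columns <- function(table) setdiff(colnames(table), "subject_id")

# Subset columns of a feature table, keeping tags in sync.
subset_features <- function(table, keep) {
  info <- feature_info(table)
  out <- table[, c("subject_id", keep), drop = FALSE]
  structure(out, feature_info = info[info$name %in% keep, , drop = FALSE],
            class = c("feature_table", "data.frame"))
}
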