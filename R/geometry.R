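#' Scene geometry for the virtual exploration scenarios
#'
#' Describes the testing room (3.50 m wide, 6.00 m long by default) and, for
#' the elevated-alley scenario, the sequence of successively narrower patches
#' (3.5, 2.5, 1.5, 0.5 m wide by default) laid along the room length. The
#' center zone defaults to an inner rectangle at 50% linear scale of the
#' room, centered (rodent open-field convention). Coordinates are metric,
#' origin at the starting-board corner, x lateral in [0, width], y
#' longitudinal in [0, length].
#'
#' @param scenario one of `"empty_room"`, `"elevated_alley"`, `"dark_maze"`.
#' @param room_width,room_length room dimensions in meters.
#' @param center_scale linear scale of the centered center zone (empty room).
#' @param patch_widths alley patch widths (m), strictly decreasing.
#' @param board_length length (m) of the starting board at the wide end.
#' @return an object of class `scene_geometry`.
#' @export
scene_geometry <- function(scenario = c("empty_room", "elevated_alley", "dark_maze"),
                           room_width = 3.5, room_length = 6.0,
                           center_scale = 0.5,
                           patch_widths = c(3.5, 2.5, 1.5, 0.5),
                           board_length = 1.0) {
  scenario <- match.arg(scenario)
  if (room_width <= 0 || room_length <= 0) stopf("room dimensions must be positive")
  if (any(diff(patch_widths) >= 0)) stopf("alley patch widths must be strictly decreasing")
  if (center_scale <= 0 || center_scale >= 1) stopf("center_scale must be in (0, 1)")
  cw <- room_width * center_scale
  cl <- room_length * center_scale
  patch_len <- room_length / length(patch_widths)
  g <- structure(list(
    scenario = scenario,
    kind = if (scenario == "elevated_alley") "alley" else "room",
    room_width = room_width,
    room_length = room_length,
    center_zone = c(x1 = (room_width - cw) / 2, x2 = (room_width + cw) / 2,
                    y1 = (room_length - cl) / 2, y2 = (room_length + cl) / 2),
    corner_points = cbind(x = c(0, room_width, room_width, 0),
                          y = c(0, 0, room_length, room_length)),
    alley_patches = data.frame(length = rep(patch_len, length(patch_widths)),
                               width = patch_widths),
    board_length = board_length
  ), class = "scene_geometry")
  g
}

# Walkable half-width at longitudinal position y (alley narrows in steps;
# a plain room has constant width).
half_width_at <- function(geometry, y) {
  if (geometry$kind != "alley") {
    return(rep(geometry$room_width / 2, length(y)))
  }
  edges <- cumsum(geometry$alley_patches$length)
  idx <- pmin(findInterval(y, c(0, edges), rightmost.closed = TRUE),
              nrow(geometry$alley_patches))
  idx[idx < 1] <- 1
  geometry$alley_patches$width[idx] / 2
}

# Clip xy positions into the walkable area.
clip_to_geometry <- function(geometry, x, y) {
  y <- pmin(pmax(y, 0), geometry$room_length)
  hw <- half_width_at(geometry, y)
  cx <- geometry$room_width / 2
  x <- pmin(pmax(x, cx - hw), cx + hw)
  list(x = x, y = y)
}

# Distance to the nearest wall of the rectangular room.
wall_distance <- function(geometry, x, y) {
  pmin(x, geometry$room_width - x, y, geometry$room_length - y)
}

in_center_zone <- function(geometry, x, y) {
  cz <- geometry$center_zone
  x >= cz["x1"] & x <= cz["x2"] & y >= cz["y1"] & y <= cz["y2"]
}

#' Latent trait profile of a synthetic subject
#'
#' Bundles the latent vulnerability trait with the behavioral and
#' physiological parameters it drives: wall-hugging (thigmotaxis) bias and
#' center avoidance for exploration, gait speed variability, mean NN
#' interval, beat-to-beat variability, respiratory sinus arrhythmia
#' amplitude and respiration rate.
#'
#' @param vulnerability latent trait, standard-normal scale.
#' @param thigmotaxis_bias probability mass of wall-band waypoints, in [0,1].
#' @param center_avoidance avoidance of exposed/center areas, in [0,1].
#' @param gait_speed_cv coefficient of variation of locomotion speed (>= 0).
#' @param mean_nn mean NN interval, ms (> 0).
#' @param nn_sd stationary SD of the AR(1) NN fluctuation, ms (>= 0).
#' @param rsa_amplitude respiratory sinus arrhythmia amplitude, ms (>= 0).
#' @param resp_rate respiration rate, breaths/min, inside [10.2, 43.8]
#'   (the 0.17-0.73 Hz band).
#' @return an object of class `trait_profile`.
#' @export
trait_profile <- function(vulnerability = 0, thigmotaxis_bias = 0.5,
                          center_avoidance = 0.5, gait_speed_cv = 0.2,
                          mean_nn = 900, nn_sd = 40, rsa_amplitude = 30,
                          resp_rate = 15) {
  if (thigmotaxis_bias < 0 || thigmotaxis_bias > 1) stopf("thigmotaxis_bias must be in [0,1]")
  if (center_avoidance < 0 || center_avoidance > 1) stopf("center_avoidance must be in [0,1]")
  if (gait_speed_cv < 0) stopf("gait_speed_cv must be >= 0")
  if (mean_nn <= 0) stopf("mean_nn must be positive")
  if (nn_sd < 0 || rsa_amplitude < 0) stopf("nn_sd and rsa_amplitude must be >= 0")
  if (resp_rate < 10.2 || resp_rate > 43.8) stopf("resp_rate must be in [10.2, 43.8] breaths/min")
  structure(list(vulnerability = vulnerability,
                 thigmotaxis_bias = thigmotaxis_bias,
                 center_avoidance = center_avoidance,
                 gait_speed_cv = gait_speed_cv,
                 mean_nn = mean_nn, nn_sd = nn_sd,
                 rsa_amplitude = rsa_amplitude, resp_rate = resp_rate),
            class = "trait_profile")
}
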