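#' Arena geometry for an open-field session
#'
#' Describes the square arena, the (uncued) goal zone and the visual cue
#' position. The coordinate origin is the southwest corner; x increases east
#' and y increases north; angles are measured counterclockwise from the
#' positive x axis (east). The default geometry is a 120 x 120 cm box with a
#' 15 cm square goal zone centered 35 cm from the west wall and 45 cm from
#' the north wall, and a cue card on the south wall.
#'
#' @param side_length Arena side length (cm).
#' @param goal_center Goal-zone center `c(x, y)` in cm.
#' @param goal_side Goal-zone side length (cm).
#' @param cue_wall Cue configuration: one of `"south"`, `"east"`, `"west"`,
#'   `"north"`, `"south+north"`.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(side_length = 120,
                           goal_center = c(35, side_length - 45),
                           goal_side = 15,
                           cue_wall = c("south", "east", "west", "north", "south+north")) {
  cue_wall <- match.arg(cue_wall)
  if (side_length <= 0) abort("side_length must be positive")
  half <- goal_side / 2
  if (any(goal_center - half < 0) || any(goal_center + half > side_length)) {
    abort("goal zone must lie fully inside the arena")
  }
  structure(
    list(
      side_length = side_length,
      goal_center = as.numeric(goal_center),
      goal_side = goal_side,
      cue_wall = cue_wall,
      center = c(side_length / 2, side_length / 2)
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %g x %g cm, goal %g cm square at (%g, %g), cue: %s\n",
    x$side_length, x$side_length, x$goal_side,
    x$goal_center[1], x$goal_center[2], x$cue_wall
  ))
  invisible(x)
}

# Square zone as a half-open box [x0, x0+side) x [y0, y0+side).
zone_square <- function(center, side) {
  list(x0 = center[1] - side / 2, y0 = center[2] - side / 2, side = side)
}

goal_zone <- function(arena) zone_square(arena$goal_center, arena$goal_side)

in_zone <- function(x, y, zone) {
  x >= zone$x0 & x < zone$x0 + zone$side &
    y >= zone$y0 & y < zone$y0 + zone$side
}

# Rotate a point counterclockwise by `deg` about `center`.
rotate_point <- function(p, deg, center) {
  th <- deg2rad(deg)
  d <- c(p[1] - center[1], p[2] - center[2])
  center + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
}

# The goal zone and its three 90-degree rotational images about the arena
# center, in rotation order 0/90/180/270 (NW, SW, SE, NE for the default
# geometry).
equivalent_zones <- function(arena) {
  lapply(c(0, 90, 180, 270), function(deg) {
    zone_square(rotate_point(arena$goal_center, deg, arena$center), arena$goal_side)
  })
}

equivalent_zone_labels <- function(arena) {
  sapply(c(0, 90, 180, 270), function(deg) {
    ctr <- rotate_point(arena$goal_center, deg, arena$center)
    paste0(
      if (ctr[2] >= arena$center[2]) "N" else "S",
      if (ctr[1] >= arena$center[1]) "E" else "W"
    )
  })
}

#' Simulation configuration for a synthetic session
#'
#' Parameters of the goal-biased correlated-random-walk trajectory generator.
#' Defaults reproduce a 20-minute session sampled at 30 Hz with a 10 s reward
#' timeout; speed and turning parameters give rat-like smooth foraging paths
#' (mean running speed around 20 cm/s).
#'
#' @param duration_s Session length (s); `duration_s * frame_rate` must be a
#'   whole number of frames.
#' @param frame_rate Tracking sampling rate (Hz).
#' @param mean_speed Mean running speed (cm/s) of the Ornstein-Uhlenbeck speed
#'   process.
#' @param speed_sd Stationary SD of the speed process (cm/s).
#' @param speed_tau Speed relaxation time constant (s).
#' @param turn_sd_deg Per-frame SD of the wrapped-Gaussian heading increment
#'   (degrees).
#' @param hd_jitter_kappa Concentration of the von Mises jitter of head
#'   direction around movement heading.
#' @param goal_bias Strength in `[0, 1]` of attraction toward the current
#'   target (goal zone, or scattered pellet after a reward); 0 gives an
#'   unbiased random walk.
#' @param reward_timeout_s Minimum interval between rewarded zone entries (s).
#' @param pellet_range Integer range `c(min, max)` of pellets per reward.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 1200, frame_rate = 30,
                       mean_speed = 20, speed_sd = 10, speed_tau = 1,
                       turn_sd_deg = 12, hd_jitter_kappa = 50,
                       goal_bias = 0.5, reward_timeout_s = 10,
                       pellet_range = c(1L, 4L)) {
  if (duration_s <= 0 || frame_rate <= 0) {
    abort("duration_s and frame_rate must be positive")
  }
  n <- duration_s * frame_rate
  if (abs(n - round(n)) > 1e-9) {
    abort("duration_s * frame_rate must be an integral number of frames")
  }
  if (goal_bias < 0 || goal_bias > 1) abort("goal_bias must lie in [0, 1]")
  structure(
    list(
      duration_s = duration_s, frame_rate = frame_rate,
      mean_speed = mean_speed, speed_sd = speed_sd, speed_tau = speed_tau,
      turn_sd_deg = turn_sd_deg, hd_jitter_kappa = hd_jitter_kappa,
      goal_bias = goal_bias, reward_timeout_s = reward_timeout_s,
      pellet_range = as.integer(pellet_range)
    ),
    class = "sim_config"
  )
}
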