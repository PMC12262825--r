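#' Detect goal-zone entries, exits and rewards
#'
#' An entry is a frame inside the zone whose predecessor is outside (zone
#' membership uses half-open bounds so edge frames are counted once). The
#' first entry is always rewarded; later entries are rewarded only if they
#' occur at least `timeout_s` after the previous reward, mirroring a reward
#' timeout that discourages rapid re-entry.
#'
#' @param tracking Tracking tibble.
#' @param zone A zone (list with `x0`, `y0`, `side`) or a numeric
#'   `c(center_x, center_y, side)`.
#' @param timeout_s Reward timeout (s).
#' @return Tibble (class `zone_events`) with one row: list-columns
#'   `entry_times`, `exit_times`, `reward_times` plus `n_entries`,
#'   `n_rewards`, `entries_per_min`, `occupancy_s`.
#' @export
detect_zone_events <- function(tracking, zone, timeout_s = 10) {
  assert_tracking(tracking)
  if (timeout_s < 0) abort("timeout_s must be >= 0")
  if (is.numeric(zone)) zone <- zone_square(zone[1:2], zone[3])
  inside <- in_zone(tracking$x_cm, tracking$y_cm, zone)
  dt <- frame_dt(tracking)
  entry_idx <- which(inside & !dplyr::lag(inside, default = TRUE))
  exit_idx <- which(!inside & dplyr::lag(inside, default = FALSE))
  entry_times <- tracking$time_s[entry_idx]
  exit_times <- tracking$time_s[exit_idx]
  rewards <- numeric(0)
  for (t in entry_times) {
    if (length(rewards) == 0 || t - rewards[length(rewards)] >= timeout_s) {
      rewards <- c(rewards, t)
    }
  }
  duration <- nrow(tracking) * dt
  n_entries <- length(entry_times)
  n_rewards <- length(rewards)
  tibble::new_tibble(
    tibble::tibble(
      entry_times = list(entry_times),
      exit_times = list(exit_times),
      reward_times = list(rewards),
      n_entries = n_entries,
      n_rewards = n_rewards,
      entries_per_min = n_entries / (duration / 60),
      occupancy_s = sum(inside) * dt
    ),
    class = "zone_events"
  )
}

#' Compare the goal zone against its rotationally equivalent zones
#'
#' Computes entries/min, occupancy and reward counts for the goal zone and
#' its three images under 90/180/270-degree rotation about the arena center.
#' Equal statistics across the four zones indicate no spatial bias; a biased
#' (goal-seeking) trajectory concentrates entries and occupancy in the goal
#' zone.
#'
#' @inheritParams detect_zone_events
#' @param arena An [arena_geometry()].
#' @return Tibble with one row per zone (rotation order 0/90/180/270;
#'   quadrant labels for the default geometry are NW, SW, SE, NE) and
#'   columns `zone`, `rotation_deg`, `is_goal`, `n_entries`,
#'   `entries_per_min`, `occupancy_s`, `n_rewards`.
#' @export
equivalent_zone_comparison <- function(tracking, arena, timeout_s = 10) {
  zones <- equivalent_zones(arena)
  labels <- equivalent_zone_labels(arena)
  purrr::map2_dfr(zones, seq_along(zones), function(z, i) {
    ev <- detect_zone_events(tracking, z, timeout_s)
    tibble::tibble(
      zone = labels[i], rotation_deg = (i - 1) * 90, is_goal = i == 1L,
      n_entries = ev$n_entries, entries_per_min = ev$entries_per_min,
      occupancy_s = ev$occupancy_s, n_rewards = ev$n_rewards
    )
  })
}

#' Approach and departure head directions around zone entries/exits
#'
#' For each zone entry, records the head direction at the start of the
#' `window_s`-long segment preceding the entry; for each exit, the head
#' direction at the end of the `window_s`-long segment following it. A
#' Rayleigh `r` near zero indicates approaches from (or departures toward)
#' uniformly distributed directions.
#'
#' @inheritParams detect_zone_events
#' @param window_s Window length (s) before entry / after exit.
#' @return List with `approach_deg`, `departure_deg` (numeric vectors),
#'   `approach_r`, `departure_r`, and `n_skipped` (events whose window fell
#'   outside the session).
#' @export
approach_departure_directions <- function(tracking, zone, window_s = 1) {
  if (window_s <= 0) abort("window_s must be positive")
  if (is.numeric(zone)) zone <- zone_square(zone[1:2], zone[3])
  ev <- detect_zone_events(tracking, zone)
  t0 <- tracking$time_s[1]
  t1 <- tracking$time_s[nrow(tracking)]
  hd_at <- function(times) {
    idx <- findInterval(times, tracking$time_s)
    tracking$hd_deg[pmax(idx, 1L)]
  }
  app_t <- ev$entry_times[[1]] - window_s
  dep_t <- ev$exit_times[[1]] + window_s
  skipped <- sum(app_t < t0) + sum(dep_t > t1)
  approach <- hd_at(app_t[app_t >= t0])
  departure <- hd_at(dep_t[dep_t <= t1])
  list(
    approach_deg = approach,
    departure_deg = departure,
    approach_r = if (length(approach) >= 2) resultant_length(approach) else NA_real_,
    departure_r = if (length(departure) >= 2) resultant_length(departure) else NA_real_,
    n_skipped = skipped
  )
}

#' Per-session behavior summary table
#'
#' @inheritParams equivalent_zone_comparison
#' @param window_s Approach/departure window (s).
#' @return Tibble: one row per zone with entries/min, occupancy, rewards,
#'   plus approach/departure Rayleigh `r` for the goal zone.
#' @export
behavior_table <- function(tracking, arena, timeout_s = 10, window_s = 1) {
  zc <- equivalent_zone_comparison(tracking, arena, timeout_s)
  ad <- approach_departure_directions(tracking, goal_zone(arena), window_s)
  zc$approach_r <- ifelse(zc$is_goal, ad$approach_r, NA_real_)
  zc$departure_r <- ifelse(zc$is_goal, ad$departure_r, NA_real_)
  zc
}
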