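# Von Mises sampler (Best & Fisher rejection algorithm); returns radians.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out
}

#' Simulate a goal-biased foraging trajectory
#'
#' Generates a correlated-random-walk trajectory through the arena at the
#' configured frame rate. Speed follows an Ornstein-Uhlenbeck process;
#' heading accumulates wrapped-Gaussian turning noise and, when
#' `goal_bias > 0`, is steered toward the current target. Targets alternate
#' between the goal zone and a uniformly scattered "pellet" location after
#' each simulated reward, emulating a place-navigation task in which zone
#' entry scatters food pellets across the floor. Walls reflect the path.
#' Head direction is the movement heading plus von Mises jitter.
#'
#' @param arena An [arena_geometry()].
#' @param config A [sim_config()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Tracking tibble with columns `time_s`, `x_cm`, `y_cm`, `hd_deg`
#'   (one row per frame) and attribute `rewards_s` (simulated reward times).
#' @export
simulate_trajectory <- function(arena, config = sim_config(), seed = 1L) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  with_seed(seed, {
    n <- as.integer(round(config$duration_s * config$frame_rate))
    dt <- 1 / config$frame_rate
    L <- arena$side_length
    gz <- goal_zone(arena)
    steer_gain <- 0.15 * config$goal_bias

    x <- y <- heading <- numeric(n)
    x[1] <- runif(1, 0.1 * L, 0.9 * L)
    y[1] <- runif(1, 0.1 * L, 0.9 * L)
    heading[1] <- runif(1, 0, 360)
    speed <- config$mean_speed

    mode <- "goal"
    target <- arena$goal_center
    pellets_left <- 0L
    rewards <- numeric(0)
    turn <- rnorm(n, 0, config$turn_sd_deg)
    margin <- 5

    for (t in 2:n) {
      # speed: OU step, clamped at zero
      speed <- speed + (config$mean_speed - speed) * dt / config$speed_tau +
        config$speed_sd * sqrt(2 * dt / config$speed_tau) * rnorm(1)
      speed <- max(speed, 0)

      h <- heading[t - 1] + turn[t]
      if (config$goal_bias > 0) {
        bearing <- rad2deg(atan2(target[2] - y[t - 1], target[1] - x[t - 1]))
        h <- h + steer_gain * circ_diff(bearing, h)
      }
      nx <- x[t - 1] + speed * dt * cos(deg2rad(h))
      ny <- y[t - 1] + speed * dt * sin(deg2rad(h))
      # reflecting walls
      if (nx < 0) { nx <- -nx; h <- 180 - h }
      if (nx > L) { nx <- 2 * L - nx; h <- 180 - h }
      if (ny < 0) { ny <- -ny; h <- -h }
      if (ny > L) { ny <- 2 * L - ny; h <- -h }
      x[t] <- min(max(nx, 0), L)
      y[t] <- min(max(ny, 0), L)
      heading[t] <- wrap_360(h)

      if (config$goal_bias > 0) {
        if (mode == "goal" && in_zone(x[t], y[t], gz)) {
          rewards <- c(rewards, (t - 1) * dt)
          pellets_left <- sample(config$pellet_range[1]:config$pellet_range[2], 1)
          target <- runif(2, margin, L - margin)
          mode <- "pellet"
        } else if (mode == "pellet" &&
                   sqrt((x[t] - target[1])^2 + (y[t] - target[2])^2) < 6) {
          pellets_left <- pellets_left - 1L
          if (pellets_left > 0L) {
            target <- runif(2, margin, L - margin)
          } else {
            mode <- "goal"
            target <- arena$goal_center
          }
        }
      }
    }

    hd <- wrap_360(heading + rad2deg(rvonmises(n, 0, config$hd_jitter_kappa)))
    out <- tibble::tibble(
      time_s = (seq_len(n) - 1) * dt,
      x_cm = x, y_cm = y, hd_deg = hd
    )
    attr(out, "rewards_s") <- rewards
    out
  })
}

#' Generate an inhomogeneous Poisson spike train from a tuning model
#'
#' Evaluates the model's instantaneous rate at every tracking frame, draws a
#' Poisson spike count per frame with mean `rate * dt`, and places spikes
#' uniformly at random within their frame.
#'
#' @inheritParams model_rate
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
generate_spikes <- function(tracking, model, arena, seed = 1L) {
  rate <- model_rate(model, tracking, arena)
  dt <- frame_dt(tracking)
  with_seed(seed, {
    counts <- rpois(length(rate), rate * dt)
    idx <- rep.int(seq_along(counts), counts)
    if (length(idx) == 0) return(numeric(0))
    sort(tracking$time_s[idx] + runif(length(idx), 0, dt))
  })
}

#' Simulate one complete session for a roster of cells
#'
#' Convenience wrapper: one trajectory plus one spike train per tuning model.
#'
#' @inheritParams simulate_trajectory
#' @param models Named list of [tuning_model()]s (names become cell ids).
#' @param id Session identifier string.
#' @param role Session role within a manipulation day.
#' @return A `session` object: list with `id`, `role`, `arena`, `tracking`,
#'   `spikes` (named list), `models`, `cells` (tibble of cell metadata).
#' @export
simulate_session <- function(arena, config, models, seed = 1L,
                             id = "session1", role = "standard1") {
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- sprintf("cell%03d", seq_along(models))
  }
  seeds <- derive_seeds(seed, length(models) + 1L)
  tracking <- simulate_trajectory(arena, config, seed = seeds[1])
  spikes <- purrr::imap(models, function(m, nm) {
    generate_spikes(tracking, m, arena, seed = seeds[1L + match(nm, names(models))])
  })
  structure(
    list(
      id = id, role = role, arena = arena, config = config,
      cue_wall = arena$cue_wall, tracking = tracking, spikes = spikes,
      models = models,
      cells = tibble::tibble(
        cell_id = names(models),
        kind = purrr::map_chr(models, "kind"),
        region = purrr::map_chr(models, "region"),
        n_spikes = lengths(spikes)
      )
    ),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s (%s), %d frames, %d cells, cue: %s\n",
              x$id, x$role, nrow(x$tracking), length(x$spikes), x$cue_wall))
  invisible(x)
}

# Cue rotation angle implied by a scenario (degrees, CCW positive).
scenario_rotation <- function(scenario) {
  switch(scenario, ccw_rotation = 90, cw_rotation = -90, duplication = 0)
}

# Effective generative model for one session of a manipulation triplet.
# Only POR-like, cue-following models respond; MEC-like models are identical
# in all three sessions.
transform_model <- function(model, scenario, role, center = c(60, 60)) {
  if (role != "manipulation" || model$region != "POR") return(model)
  if (scenario %in% c("ccw_rotation", "cw_rotation")) {
    if (model$kind == "lm_hd") {
      model$preferred_deg <- wrap_360(model$preferred_deg +
                                        model$cue_gain * scenario_rotation(scenario))
    } else if (model$kind == "cb_x_hd") {
      gain <- model$cue_gain %||% 1
      ang <- gain * scenario_rotation(scenario)
      model$reference <- rotate_point(model$reference, ang, center)
      model$hd_preferred_deg <- wrap_360(model$hd_preferred_deg + ang)
    }
  } else if (scenario == "duplication" && model$kind == "lm_hd") {
    model$lobe_weight <- model$duplication_weight
  }
  model
}

#' Simulate a standard / manipulation / standard cue-session triplet
#'
#' Produces three sessions sharing one cell roster. Sessions 1 and 3 use the
#' standard south cue; session 2 moves the cue to the east wall
#' (`ccw_rotation`, +90 degrees), the west wall (`cw_rotation`, -90 degrees)
#' or duplicates it on the north wall (`duplication`). Landmark-modulated HD
#' models rotate their preferred direction by `cue_gain` times the cue
#' rotation, or split into two lobes 180 degrees apart weighted by
#' `duplication_weight`; cue-following conjunctive CB x HD models rotate
#' their egocentric reference point about the arena center by the same
#' gained angle. MEC-like models are generated identically in all sessions.
#'
#' @inheritParams simulate_session
#' @param scenario One of `"ccw_rotation"`, `"cw_rotation"`, `"duplication"`.
#' @return A `session_triplet`: list of three `session`s plus `scenario`.
#' @export
simulate_cue_triplet <- function(arena, config, models,
                                 scenario = c("ccw_rotation", "cw_rotation",
                                              "duplication"),
                                 seed = 1L) {
  scenario <- match.arg(scenario)
  roles <- c("standard1", "manipulation", "standard2")
  walls <- switch(scenario,
    ccw_rotation = c("south", "east", "south"),
    cw_rotation = c("south", "west", "south"),
    duplication = c("south", "south+north", "south")
  )
  seeds <- derive_seeds(seed, 3L)
  sessions <- purrr::map(1:3, function(k) {
    ar <- arena
    ar$cue_wall <- walls[k]
    eff <- purrr::map(models, transform_model, scenario = scenario,
                      role = roles[k], center = arena$center)
    simulate_session(ar, config, eff, seed = seeds[k],
                     id = paste0("s", k), role = roles[k])
  })
  structure(list(sessions = sessions, scenario = scenario),
            class = "session_triplet")
}

#' @export
print.session_triplet <- function(x, ...) {
  cat(sprintf("<session_triplet> scenario %s, %d cells\n",
              x$scenario, length(x$sessions[[1]]$spikes)))
  invisible(x)
}
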