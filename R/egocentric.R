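#' Egocentric bearing of a reference point
#'
#' The angle at which a reference point lies relative to the animal's
#' heading: 0 degrees is directly ahead, +90 degrees is to the animal's left
#' (counterclockwise positive, consistent with head direction measured
#' counterclockwise from the positive x axis). Samples closer than
#' `min_dist` to the reference point get `NA` (the bearing is ill-defined at
#' zero distance).
#'
#' @param x,y Position (cm); vectors.
#' @param hd_deg Head direction (degrees).
#' @param reference Reference point `c(x, y)` in cm.
#' @param min_dist Exclusion radius (cm).
#' @return Bearings in degrees wrapped to `[-180, 180)`; `NA` within the
#'   exclusion radius.
#' @export
egocentric_bearing <- function(x, y, hd_deg, reference, min_dist = 1) {
  dx <- reference[1] - x
  dy <- reference[2] - y
  b <- wrap_180(rad2deg(atan2(dy, dx)) - hd_deg)
  b[sqrt(dx^2 + dy^2) < min_dist] <- NA_real_
  b
}

#' Egocentric-bearing MVL map over a grid of candidate reference points
#'
#' For each of `n_grid^2` reference points (centers of an even partition of
#' the arena), builds a 12-degree-bin egocentric-bearing tuning curve and
#' records its mean vector length and preferred bearing. The reference point
#' with the highest MVL (`mvl_max` location) estimates the cell's preferred
#' egocentric reference location; for a center-bearing cell it falls at the
#' arena center, while conjunctive CB x HD cells put it elsewhere.
#' Reference points whose tuning curve leaves more than half of the bearing
#' bins unoccupied get `NA`.
#'
#' @inheritParams compute_rate_map
#' @param n_grid Reference points per side (20 gives a 6 cm pitch on the
#'   default arena, inset 3 cm from the walls).
#' @param bin_width Bearing bin width (degrees).
#' @param min_coverage Minimum fraction of occupied bearing bins.
#' @return Object of class `mvl_map`: `mvl` and `preferred` matrices
#'   (`[x, y]`), `x_centers`/`y_centers`, `mvl_max` value, `mvl_max_loc`
#'   (cm), and `normalized` (map divided by its maximum).
#' @export
mvl_map <- function(tracking, spikes, arena, n_grid = 20, bin_width = 12,
                    min_coverage = 0.5) {
  assert_tracking(tracking)
  pitch <- arena$side_length / n_grid
  centers <- (seq_len(n_grid) - 0.5) * pitch
  dt <- frame_dt(tracking)
  n_bins <- round(360 / bin_width)
  sp_frames <- spikes_to_frames(spikes, tracking$time_s, dt)
  sp_frames <- sp_frames[!is.na(sp_frames)]

  mvl_m <- pref_m <- matrix(NA_real_, n_grid, n_grid)
  for (j in seq_len(n_grid)) {
    for (i in seq_len(n_grid)) {
      b <- egocentric_bearing(tracking$x_cm, tracking$y_cm, tracking$hd_deg,
                              c(centers[i], centers[j]))
      fb <- floor(wrap_360(b) / bin_width) + 1L
      fb[fb > n_bins] <- n_bins
      occ <- tabulate(fb[!is.na(fb)], nbins = n_bins) * dt
      if (mean(occ > 0) < min_coverage) next
      sb <- fb[sp_frames]
      cnt <- tabulate(sb[!is.na(sb)], nbins = n_bins)
      rate <- ifelse(occ > 0, cnt / occ, NA_real_)
      mv <- curve_mvl(rate, (seq_len(n_bins) - 0.5) * bin_width)
      mvl_m[i, j] <- mv$mvl
      pref_m[i, j] <- mv$preferred_deg
    }
  }
  if (all(is.na(mvl_m))) abort("MVL undefined at every reference point")
  best <- which.max(mvl_m)  # column-major argmax; first index on ties
  bi <- (best - 1L) %% n_grid + 1L
  bj <- (best - 1L) %/% n_grid + 1L
  structure(
    list(
      mvl = mvl_m, preferred = pref_m,
      x_centers = centers, y_centers = centers, pitch = pitch,
      mvl_max = mvl_m[best],
      mvl_max_loc = c(centers[bi], centers[bj]),
      normalized = mvl_m / mvl_m[best]
    ),
    class = "mvl_map"
  )
}

#' @export
print.mvl_map <- function(x, ...) {
  cat(sprintf("<mvl_map> %d x %d refs, MVL_max %.3f at (%g, %g) cm\n",
              nrow(x$mvl), ncol(x$mvl), x$mvl_max,
              x$mvl_max_loc[1], x$mvl_max_loc[2]))
  invisible(x)
}

#' @rdname tidy_openfieldr
#' @export
tidy.mvl_map <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$x_centers), j = seq_along(x$y_centers))
  tibble::tibble(
    x_cm = x$x_centers[grid$i], y_cm = x$y_centers[grid$j],
    mvl = x$mvl[cbind(grid$i, grid$j)],
    preferred_deg = x$preferred[cbind(grid$i, grid$j)]
  )
}

#' Population summary of egocentric MVL maps
#'
#' @param maps List of [mvl_map()] objects on a common grid.
#' @param arena Optional [arena_geometry()]; when given, per-zone mean MVL
#'   (goal zone vs rotationally equivalent zones) is included.
#' @return List with `mvl_max_histogram` (counts per reference point),
#'   `mean_normalized` (element-wise mean of normalized maps), and
#'   optionally `zone_mvl` (tibble of per-zone mean MVL).
#' @export
population_mvl_summary <- function(maps, arena = NULL) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  hist_m <- matrix(0L, nrow(ref$mvl), ncol(ref$mvl))
  acc <- matrix(0, nrow(ref$mvl), ncol(ref$mvl))
  cnt <- matrix(0, nrow(ref$mvl), ncol(ref$mvl))
  for (m in maps) {
    i <- which.min(abs(ref$x_centers - m$mvl_max_loc[1]))
    j <- which.min(abs(ref$y_centers - m$mvl_max_loc[2]))
    hist_m[i, j] <- hist_m[i, j] + 1L
    ok <- !is.na(m$normalized)
    acc[ok] <- acc[ok] + m$normalized[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  mean_norm <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out <- list(mvl_max_histogram = hist_m, mean_normalized = mean_norm,
              x_centers = ref$x_centers, y_centers = ref$y_centers)
  if (!is.null(arena)) {
    zones <- equivalent_zones(arena)
    labels <- equivalent_zone_labels(arena)
    grid <- expand.grid(i = seq_along(ref$x_centers), j = seq_along(ref$y_centers))
    gx <- ref$x_centers[grid$i]; gy <- ref$y_centers[grid$j]
    out$zone_mvl <- purrr::map2_dfr(zones, seq_along(zones), function(z, k) {
      inz <- in_zone(gx, gy, z)
      tibble::tibble(
        zone = labels[k], rotation_deg = (k - 1) * 90, is_goal = k == 1L,
        mean_mvl = mean(mean_norm[cbind(grid$i, grid$j)][inz], na.rm = TRUE)
      )
    })
  }
  out
}

#' Signed rotation of an MVL_max location about the arena center
#'
#' The counterclockwise angle from `loc_a - center` to `loc_b - center`,
#' wrapped to `[-180, 180)`. Used to quantify how far a cell's egocentric
#' reference point rotated between a standard and a cue-manipulation
#' session.
#'
#' @param loc_a,loc_b Locations `c(x, y)` in cm.
#' @param center Rotation center (cm).
#' @return Signed angle in degrees; `NA` if either location coincides with
#'   the center.
#' @export
mvlmax_rotation_about_center <- function(loc_a, loc_b, center) {
  va <- loc_a - center
  vb <- loc_b - center
  if (sqrt(sum(va^2)) < 1e-9 || sqrt(sum(vb^2)) < 1e-9) return(NA_real_)
  wrap_180(rad2deg(atan2(vb[2], vb[1]) - atan2(va[2], va[1])))
}
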