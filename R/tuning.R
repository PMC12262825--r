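#' Circular (head-direction or bearing) tuning curve
#'
#' Bins a per-frame angular variable into fixed-width bins, divides the spike
#' count in each bin by its occupancy time, and summarizes the curve by its
#' mean vector length (MVL) and preferred direction (see [curve_mvl()]).
#'
#' @param tracking Tracking tibble.
#' @param spikes Spike times (s).
#' @param angles Per-frame angles in degrees; defaults to `tracking$hd_deg`.
#'   `NA` angles (e.g. ill-defined bearings) exclude the frame and its spikes.
#' @param bin_width Bin width in degrees (12 gives 30 bins).
#' @param variable Label for the angular variable (`"hd"`,
#'   `"center_bearing"`, `"egocentric_bearing"`).
#' @return A tibble of class `circ_tuning` (`bin_center_deg`, `occupancy_s`,
#'   `n_spikes`, `rate_hz`) with attributes `mvl`, `preferred_deg`,
#'   `peak_rate`, `bin_width`, `variable`.
#' @export
circular_tuning_curve <- function(tracking, spikes, angles = NULL,
                                  bin_width = 12, variable = "hd") {
  assert_tracking(tracking)
  angles <- angles %||% tracking$hd_deg
  if (length(angles) != nrow(tracking)) {
    abort("angles must have one value per tracking frame")
  }
  dt <- frame_dt(tracking)
  n_bins <- round(360 / bin_width)
  frame_bin <- floor(wrap_360(angles) / bin_width) + 1L
  frame_bin[frame_bin > n_bins] <- n_bins  # guard wrap_360 returning 360 - eps
  ok <- !is.na(frame_bin)
  occ <- tabulate(frame_bin[ok], nbins = n_bins) * dt

  sp_frames <- spikes_to_frames(spikes, tracking$time_s, dt)
  sp_bin <- frame_bin[sp_frames[!is.na(sp_frames)]]
  cnt <- tabulate(sp_bin[!is.na(sp_bin)], nbins = n_bins)

  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  mv <- curve_mvl(rate, centers)
  out <- tibble::new_tibble(
    tibble::tibble(
      bin_center_deg = centers, occupancy_s = occ,
      n_spikes = cnt, rate_hz = rate
    ),
    class = "circ_tuning"
  )
  attr(out, "mvl") <- mv$mvl
  attr(out, "preferred_deg") <- mv$preferred_deg
  attr(out, "peak_rate") <- if (all(is.na(rate))) NA_real_ else max(rate, na.rm = TRUE)
  attr(out, "bin_width") <- bin_width
  attr(out, "variable") <- variable
  out
}

#' MVL of a circular tuning curve
#' @param curve A `circ_tuning` tibble.
#' @return Numeric scalar (`NA` when the curve has no rate mass).
#' @export
mvl <- function(curve) attr(curve, "mvl")

#' Preferred direction of a circular tuning curve (degrees)
#' @inheritParams mvl
#' @export
preferred_direction <- function(curve) attr(curve, "preferred_deg")

#' Center-distance tuning curve with linear and Gaussian fits
#'
#' Bins firing rate by the animal's distance from the arena center and fits
#' both a straight line and a Gaussian (amplitude, mean, width, offset) to
#' the occupied bins by least squares, returning the R-squared of each fit
#' as a tuning-strength measure.
#'
#' @inheritParams circular_tuning_curve
#' @param arena An [arena_geometry()].
#' @param bin_width Distance bin width (cm).
#' @return Tibble of class `dist_tuning` (`bin_center_cm`, `occupancy_s`,
#'   `n_spikes`, `rate_hz`) with attributes `linear_r2`, `gaussian_r2`,
#'   `linear_slope`, `gaussian_pars`, `peak_rate`.
#' @export
distance_tuning_curve <- function(tracking, spikes, arena, bin_width = 4) {
  assert_tracking(tracking)
  ctr <- arena$center
  d <- sqrt((tracking$x_cm - ctr[1])^2 + (tracking$y_cm - ctr[2])^2)
  dmax <- arena$side_length / sqrt(2)
  n_bins <- ceiling(dmax / bin_width)
  dt <- frame_dt(tracking)
  frame_bin <- pmin(floor(d / bin_width) + 1L, n_bins)
  occ <- tabulate(frame_bin, nbins = n_bins) * dt
  sp_frames <- spikes_to_frames(spikes, tracking$time_s, dt)
  cnt <- tabulate(frame_bin[sp_frames[!is.na(sp_frames)]], nbins = n_bins)
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  centers <- (seq_len(n_bins) - 0.5) * bin_width

  vis <- !is.na(rate)
  xc <- centers[vis]; yc <- rate[vis]
  lin_r2 <- NA_real_; slope <- NA_real_
  gauss_r2 <- NA_real_; gpars <- NULL
  if (sum(vis) >= 3) {
    sst <- sum((yc - mean(yc))^2)
    fit <- stats::lm(yc ~ xc)
    slope <- unname(coef(fit)[2])
    lin_r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
    gfit <- tryCatch(
      minpack.lm::nlsLM(
        yc ~ c0 + a * exp(-(xc - m)^2 / (2 * s^2)),
        start = list(c0 = min(yc), a = max(yc) - min(yc),
                     m = xc[which.max(yc)], s = diff(range(xc)) / 4),
        lower = c(0, 0, 0, bin_width / 4),
        upper = c(Inf, Inf, dmax, dmax),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(gfit)) {
      gauss_r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(gfit)^2) / sst
      gpars <- as.list(coef(gfit))
    }
  }
  out <- tibble::new_tibble(
    tibble::tibble(
      bin_center_cm = centers, occupancy_s = occ,
      n_spikes = cnt, rate_hz = rate
    ),
    class = "dist_tuning"
  )
  attr(out, "linear_r2") <- lin_r2
  attr(out, "gaussian_r2") <- gauss_r2
  attr(out, "linear_slope") <- slope
  attr(out, "gaussian_pars") <- gpars
  attr(out, "peak_rate") <- if (all(is.na(rate))) NA_real_ else max(rate, na.rm = TRUE)
  out
}

#' Circularly shift a spike train in time
#'
#' Adds a uniform random shift of at least `min_shift` seconds to every spike
#' time, wrapping times beyond the session end back to the beginning. The
#' shifted train keeps the cell's temporal structure (inter-spike intervals,
#' up to one wrap point) while decoupling it from behavior; it is the null
#' model for all shuffle-based significance thresholds.
#'
#' @param spikes Spike times (s).
#' @param session_duration Session length (s); must exceed `2 * min_shift`.
#' @param min_shift Minimum shift (s).
#' @param seed Integer seed.
#' @param shift Optional fixed shift (s) overriding the random draw.
#' @return Sorted shifted spike times.
#' @export
shuffle_spike_train <- function(spikes, session_duration, min_shift = 30,
                                seed = NULL, shift = NULL) {
  if (session_duration <= 2 * min_shift) {
    abort("session_duration must exceed 2 * min_shift")
  }
  shift <- shift %||% with_seed(seed, runif(1, min_shift, session_duration - min_shift))
  sort((spikes + shift) %% session_duration)
}

#' Within-cell shuffle significance threshold
#'
#' Computes `statistic_fn` on `n_shuffles` circularly time-shifted copies of
#' the spike train and returns the requested percentile of the null
#' distribution (the within-cell 99th percentile by default).
#'
#' @param spikes Spike times (s).
#' @param session_duration Session length (s).
#' @param statistic_fn Function of a spike-time vector returning a scalar.
#' @param n_shuffles Number of shifted trains.
#' @param percentile Percentile of the null distribution (0-100).
#' @param min_shift Minimum shift (s).
#' @param seed Integer seed.
#' @return List with `threshold` and the vector of `null_values`.
#' @export
shuffle_threshold <- function(spikes, session_duration, statistic_fn,
                              n_shuffles = 400, percentile = 99,
                              min_shift = 30, seed = 1L) {
  shifts <- with_seed(seed, runif(n_shuffles, min_shift, session_duration - min_shift))
  vals <- vapply(shifts, function(s) {
    v <- statistic_fn(shuffle_spike_train(spikes, session_duration, min_shift,
                                          shift = s))
    if (length(v) != 1) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.10) {
    abort("statistic undefined on more than 10% of shuffles")
  }
  list(
    threshold = unname(quantile(vals, percentile / 100, na.rm = TRUE)),
    null_values = vals
  )
}

# Fast shuffle threshold for binned-circular-curve MVL: the per-frame angle
# bins and occupancy are shift-invariant, so each of the 400 shifts only
# re-bins the spikes. Numerically identical to shuffle_threshold() with an
# mvl(circular_tuning_curve(...)) statistic.
shuffle_threshold_curve_mvl <- function(tracking, spikes, angles = NULL,
                                        bin_width = 12, n_shuffles = 400,
                                        percentile = 99, min_shift = 30,
                                        seed = 1L) {
  angles <- angles %||% tracking$hd_deg
  dt <- frame_dt(tracking)
  duration <- nrow(tracking) * dt
  if (duration <= 2 * min_shift) {
    abort("session duration must exceed 2 * min_shift")
  }
  n_bins <- round(360 / bin_width)
  frame_bin <- floor(wrap_360(angles) / bin_width) + 1L
  frame_bin[frame_bin > n_bins] <- n_bins
  occ <- tabulate(frame_bin[!is.na(frame_bin)], nbins = n_bins) * dt
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  time_s <- tracking$time_s
  shifts <- with_seed(seed, runif(n_shuffles, min_shift, duration - min_shift))
  vals <- vapply(shifts, function(s) {
    idx <- spikes_to_frames((spikes + s) %% duration, time_s, dt)
    sb <- frame_bin[idx[!is.na(idx)]]
    cnt <- tabulate(sb[!is.na(sb)], nbins = n_bins)
    curve_mvl(ifelse(occ > 0, cnt / occ, NA_real_), centers)$mvl
  }, numeric(1))
  unname(quantile(vals, percentile / 100, na.rm = TRUE))
}

# Fast shuffle threshold for spatial information: occupancy, bin geometry
# and smoothing operators are shift-invariant; each shift re-bins spikes and
# re-smooths the count map only.
shuffle_threshold_si <- function(tracking, spikes, arena, bin_size = 2.5,
                                 smooth_sigma = 3.75, n_shuffles = 400,
                                 percentile = 99, min_shift = 30, seed = 1L) {
  n_bins <- ceiling(arena$side_length / bin_size)
  dt <- frame_dt(tracking)
  duration <- nrow(tracking) * dt
  if (duration <= 2 * min_shift) {
    abort("session duration must exceed 2 * min_shift")
  }
  bx <- pmin(pmax(floor(tracking$x_cm / bin_size), 0), n_bins - 1) + 1L
  by <- pmin(pmax(floor(tracking$y_cm / bin_size), 0), n_bins - 1) + 1L
  lin <- (by - 1L) * n_bins + bx
  occ <- matrix(tabulate(lin, nbins = n_bins^2) * dt, n_bins, n_bins)
  visited <- occ > 0
  sigma_bins <- smooth_sigma / bin_size
  A <- gauss_band(n_bins, sigma_bins)
  den <- A %*% (visited + 0) %*% t(A)
  occ_na <- occ; occ_na[!visited] <- NA_real_
  occ_sm <- smooth_map_nan(occ_na, sigma_bins)
  p <- occ_sm / sum(occ_sm, na.rm = TRUE)
  time_s <- tracking$time_s
  shifts <- with_seed(seed, runif(n_shuffles, min_shift, duration - min_shift))
  vals <- vapply(shifts, function(s) {
    idx <- spikes_to_frames((spikes + s) %% duration, time_s, dt)
    cnt <- matrix(tabulate(lin[idx[!is.na(idx)]], nbins = n_bins^2),
                  n_bins, n_bins)
    raw <- matrix(0, n_bins, n_bins)
    raw[visited] <- cnt[visited] / occ[visited]
    Ri <- (A %*% raw %*% t(A)) / den
    Ri[!visited] <- NA_real_
    R <- sum(p * Ri, na.rm = TRUE)
    if (!is.finite(R) || R <= 0) return(NA_real_)
    term <- p * (Ri / R) * log2(Ri / R)
    term[!is.na(Ri) & Ri == 0] <- 0
    sum(term, na.rm = TRUE)
  }, numeric(1))
  unname(quantile(vals, percentile / 100, na.rm = TRUE))
}

#' Resample tracking and spikes to equalize spatial occupancy
#'
#' Tiles the arena with coarse square bins, finds the minimum occupancy over
#' visited bins, and subsamples frames (without replacement) within every bin
#' down to that minimum; spikes are retained iff their frame is retained.
#' This controls for goal-directed occupancy bias before egocentric-bearing
#' or spatial firing analyses. Bins never visited are excluded from the
#' minimum and from the output.
#'
#' @inheritParams distance_tuning_curve
#' @param bin_size Resampling bin side (cm); 15 cm tiles the default arena
#'   with 64 bins.
#' @param seed Integer seed.
#' @return List with elements `tracking` (subset, original timestamps) and
#'   `spikes`.
#' @export
resample_equal_occupancy <- function(tracking, spikes, arena,
                                     bin_size = 15, seed = 1L) {
  assert_tracking(tracking)
  n_bins <- ceiling(arena$side_length / bin_size)
  bx <- pmin(pmax(floor(tracking$x_cm / bin_size), 0), n_bins - 1) + 1L
  by <- pmin(pmax(floor(tracking$y_cm / bin_size), 0), n_bins - 1) + 1L
  lin <- (by - 1L) * n_bins + bx
  counts <- tabulate(lin, nbins = n_bins * n_bins)
  visited <- which(counts > 0)
  target <- min(counts[visited])
  keep <- with_seed(seed, {
    unlist(lapply(visited, function(b) {
      idx <- which(lin == b)
      if (length(idx) > target) sample(idx, target) else idx
    }))
  })
  keep <- sort(keep)
  dt <- frame_dt(tracking)
  sp_frames <- spikes_to_frames(spikes, tracking$time_s, dt)
  sp_keep <- !is.na(sp_frames) & sp_frames %in% keep
  out_tracking <- tracking[keep, ]
  attr(out_tracking, "dt") <- dt
  list(tracking = out_tracking, spikes = spikes[sp_keep])
}
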