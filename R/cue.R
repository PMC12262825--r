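#' Bidirectionality index of head-direction tuning
#'
#' Builds two HD tuning curves: one from the actual head directions and one
#' after doubling each frame's HD (mod 360). A symmetric two-lobed
#' (bidirectional) tuning curve collapses to a single lobe under angle
#' doubling, so its doubled-curve MVL exceeds its normal MVL. The index is
#' `BI = (MVL_doubled - MVL_normal) / (MVL_doubled + MVL_normal)`: +1 for a
#' perfectly symmetric bimodal curve, negative for unidirectional tuning.
#' BI is invariant to uniform rate scaling.
#'
#' @inheritParams circular_tuning_curve
#' @return Tibble with `mvl_normal`, `mvl_doubled`, `bi`.
#' @export
bidirectionality_index <- function(tracking, spikes, bin_width = 12) {
  c_n <- circular_tuning_curve(tracking, spikes, bin_width = bin_width)
  c_d <- circular_tuning_curve(tracking, spikes,
                               angles = wrap_360(2 * tracking$hd_deg),
                               bin_width = bin_width, variable = "hd_doubled")
  m_n <- mvl(c_n); m_d <- mvl(c_d)
  bi <- if (is.na(m_n) || is.na(m_d) || m_n + m_d == 0) NA_real_ else {
    (m_d - m_n) / (m_d + m_n)
  }
  tibble::tibble(mvl_normal = m_n, mvl_doubled = m_d, bi = bi)
}

vm_unit <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - mu_deg)) - 1))
}

#' Fit a bidirectional von Mises function to a tuning curve
#'
#' Least-squares fit of `offset + A1 vm(theta; mu, kappa) + A2 vm(theta;
#' mu + 180, kappa)` (amplitudes subtracted instead of added in trough
#' mode) to a binned circular tuning curve, with the two lobes exactly 180
#' degrees apart and a shared concentration. The optimizer is restarted
#' from 12 evenly spaced initial lobe directions and the best-loss fit is
#' returned.
#'
#' @param curve A `circ_tuning` tibble (>= 30 bins recommended).
#' @param mode `"peak"` (upright lobes) or `"trough"` (inverted lobes).
#' @return Object of class `vm_fit`: `mu_deg` (first lobe), `kappa`,
#'   `amplitudes` (length 2), `offset`, `mode`, `max_fit`, `min_fit`,
#'   `r_squared`, and `fitted_fn(theta_deg)`.
#' @export
fit_bidirectional_von_mises <- function(curve, mode = c("peak", "trough")) {
  mode <- match.arg(mode)
  th <- curve$bin_center_deg
  y <- curve$rate_hz
  ok <- !is.na(y)
  th <- th[ok]; y <- y[ok]
  if (length(y) < 8) abort("too few occupied bins for a von Mises fit")
  sgn <- if (mode == "peak") 1 else -1
  loss <- function(p) {
    pred <- p[4] + sgn * (p[2] * vm_unit(th, p[1], p[3]) +
                            p[5] * vm_unit(th, p[1] + 180, p[3]))
    sum((y - pred)^2)
  }
  span <- max(y) - min(y)
  base <- if (mode == "peak") min(y) else max(y)
  best <- NULL
  for (mu0 in seq(0, 330, by = 30)) {
    o <- optim(c(mu0, span, 2, base, span / 2), loss, method = "L-BFGS-B",
               lower = c(-360, 0, 0.05, 0, 0), upper = c(720, Inf, 50, Inf, Inf),
               control = list(maxit = 300))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  fitted_fn <- function(theta_deg) {
    p[4] + sgn * (p[2] * vm_unit(theta_deg, p[1], p[3]) +
                    p[5] * vm_unit(theta_deg, p[1] + 180, p[3]))
  }
  grid_th <- seq(0, 359.5, by = 0.5)
  fg <- fitted_fn(grid_th)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      mu_deg = wrap_360(p[1]), kappa = p[3],
      amplitudes = c(p[2], p[5]), offset = p[4], mode = mode,
      max_fit = max(fg), min_fit = min(fg),
      r_squared = if (sst == 0) 0 else 1 - best$value / sst,
      sse = best$value, fitted_fn = fitted_fn
    ),
    class = "vm_fit"
  )
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf(
    "<vm_fit> %s lobes at %.1f / %.1f deg, kappa %.2f, A = (%.2f, %.2f), R2 = %.3f\n",
    x$mode, x$mu_deg, wrap_360(x$mu_deg + 180), x$kappa,
    x$amplitudes[1], x$amplitudes[2], x$r_squared
  ))
  invisible(x)
}

#' @rdname tidy_openfieldr
#' @export
tidy.vm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu_deg", "mu_opposite_deg", "kappa", "amplitude1", "amplitude2",
             "offset"),
    estimate = c(x$mu_deg, wrap_360(x$mu_deg + 180), x$kappa,
                 x$amplitudes[1], x$amplitudes[2], x$offset)
  )
}

#' @rdname tidy_openfieldr
#' @export
glance.vm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, sse = x$sse, mode = x$mode,
                 max_fit = x$max_fit, min_fit = x$min_fit)
}

#' Cue modulation indices from a bidirectional von Mises fit
#'
#' The fitted lobe circularly nearest the cell's session-1 preferred (or
#' trough) direction is attributed to the original south cue; the opposite
#' lobe to the added north cue. For peak fits
#' `MI = (P - Min_fit) / Max_fit` with `P` the fitted rate at the lobe; for
#' trough fits `MI = (Max_fit - T) / Max_fit`. Both indices lie in
#' `[0, 1]`.
#'
#' @param fit A [fit_bidirectional_von_mises()] result.
#' @param session1_preferred_deg Preferred (or trough) direction from the
#'   initial standard session, degrees.
#' @return Tibble with `mi_south`, `mi_north`, `south_lobe_deg`.
#' @export
cue_modulation_indices <- function(fit, session1_preferred_deg) {
  if (fit$max_fit <= 0) {
    return(tibble::tibble(mi_south = NA_real_, mi_north = NA_real_,
                          south_lobe_deg = NA_real_))
  }
  lobes <- wrap_360(c(fit$mu_deg, fit$mu_deg + 180))
  dist <- abs(circ_diff(lobes, session1_preferred_deg))
  south <- lobes[which.min(dist)]
  north <- lobes[which.max(dist)]
  mi_of <- function(lobe) {
    v <- fit$fitted_fn(lobe)
    if (fit$mode == "peak") (v - fit$min_fit) / fit$max_fit
    else (fit$max_fit - v) / fit$max_fit
  }
  tibble::tibble(
    mi_south = mi_of(south), mi_north = mi_of(north), south_lobe_deg = south
  )
}

#' Shift in preferred firing direction between two tuning curves
#'
#' Circular difference (curve 2 minus curve 1) of the preferred directions,
#' wrapped to `[-180, 180)` with counterclockwise positive (so a 270-degree
#' rotation reports as -90).
#'
#' @param curve1,curve2 `circ_tuning` tibbles.
#' @return Signed shift in degrees (`NA` if either preferred direction is
#'   undefined).
#' @export
preferred_direction_shift <- function(curve1, curve2) {
  p1 <- preferred_direction(curve1)
  p2 <- preferred_direction(curve2)
  if (is.na(p1) || is.na(p2)) return(NA_real_)
  circ_diff(p2, p1)
}

rot90_ccw <- function(m) t(m[, ncol(m):1, drop = FALSE])

#' Correlations between a rate map and 90-degree rotations of another
#'
#' Pearson correlation over mutually visited bins between `map1` and `map2`
#' rotated by 0/90/180/270 degrees about the arena center. Allocentric maps
#' anchored to the room correlate best at 0 degrees across a cue rotation;
#' maps that follow the cue correlate best at the cue's rotation angle.
#'
#' @param map1,map2 [compute_rate_map()] results with the same (square)
#'   geometry.
#' @param min_overlap Minimum common visited bins.
#' @return Tibble with `rotation_deg` and `correlation` (NA when too few
#'   common bins).
#' @export
rotated_map_correlations <- function(map1, map2, min_overlap = 20) {
  M1 <- if (inherits(map1, "rate_map")) map1$rate else map1
  M2 <- if (inherits(map2, "rate_map")) map2$rate else map2
  stopifnot(nrow(M1) == ncol(M1), all(dim(M1) == dim(M2)))
  purrr::map_dfr(0:3, function(k) {
    R <- M2
    for (i in seq_len(k)) R <- rot90_ccw(R)
    ok <- !is.na(M1) & !is.na(R)
    r <- if (sum(ok) < min_overlap) NA_real_ else stats::cor(M1[ok], R[ok])
    tibble::tibble(rotation_deg = k * 90, correlation = r)
  })
}
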