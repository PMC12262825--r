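#' Mean vector length and mean direction of a binned circular tuning curve
#'
#' The tuning strength of a circular (head-direction or bearing) tuning curve
#' is summarized by the length of the rate-weighted mean resultant vector over
#' bin centers: \eqn{MVL = |\sum_b r_b e^{i\theta_b}| / \sum_b r_b}. The
#' preferred direction is the argument of the same sum.
#'
#' @param rates Firing rate per bin (Hz); `NA` bins are dropped.
#' @param bin_centers_deg Bin center angles in degrees.
#' @return A list with elements `mvl` (in `[0, 1]`) and `preferred_deg`
#'   (in `[0, 360)`); both `NA` when the curve carries no rate mass.
#' @export
curve_mvl <- function(rates, bin_centers_deg) {
  keep <- !is.na(rates)
  r <- rates[keep]
  th <- deg2rad(bin_centers_deg[keep])
  tot <- sum(r)
  if (length(r) == 0 || tot <= 0) {
    return(list(mvl = NA_real_, preferred_deg = NA_real_))
  }
  z <- sum(r * exp(1i * th)) / tot
  list(mvl = Mod(z), preferred_deg = wrap_360(rad2deg(Arg(z))))
}

# Mean resultant length of raw angles (degrees).
resultant_length <- function(angles_deg) {
  Mod(mean(exp(1i * deg2rad(angles_deg))))
}

#' Rayleigh test for circular uniformity
#'
#' Tests whether a sample of angles is clustered around some (unspecified)
#' direction. The P value uses the \eqn{Z = n r^2} large-sample approximation
#' with the first-order finite-sample correction
#' \eqn{P = e^{-Z}\,[1 + (2Z - Z^2)/(4n)]}.
#'
#' @param angles_deg Angles in degrees (n >= 2).
#' @return Tibble with columns `r`, `mean_deg`, `z`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 2) abort("rayleigh_test requires at least 2 angles")
  z_mean <- mean(exp(1i * deg2rad(angles_deg)))
  r <- Mod(z_mean)
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
  p <- min(max(p, 0), 1)
  tibble::tibble(
    r = r, mean_deg = wrap_360(rad2deg(Arg(z_mean))),
    z = Z, p_value = p, n = n
  )
}

#' V test for circular concentration around a predicted direction
#'
#' A modified Rayleigh test that is sensitive to clustering around a direction
#' specified in advance (for example the +90 degrees shift expected from a
#' counterclockwise cue rotation). `u` is the normalized statistic
#' \eqn{u = V \sqrt{2/n}} with \eqn{V = n r \cos(\bar\theta - \mu)}; the P
#' value is its one-sided normal approximation.
#'
#' @param angles_deg Angles in degrees (n >= 2).
#' @param mu_deg Predicted direction in degrees.
#' @return Tibble with columns `u`, `v`, `r`, `mean_deg`, `p_value`, `n`.
#' @export
v_test <- function(angles_deg, mu_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 2) abort("v_test requires at least 2 angles")
  z_mean <- mean(exp(1i * deg2rad(angles_deg)))
  r <- Mod(z_mean)
  mean_deg <- rad2deg(Arg(z_mean))
  v <- n * r * cos(deg2rad(mean_deg - mu_deg))
  u <- v * sqrt(2 / n)
  tibble::tibble(
    u = u, v = v, r = r, mean_deg = wrap_360(mean_deg),
    p_value = stats::pnorm(u, lower.tail = FALSE), n = n
  )
}
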