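# Full 2D cross-correlation sum C(d) = sum_t A(t) B(t + d) for all integer
# shifts, via zero-padded FFTs. Returns a (2nx-1) x (2ny-1) matrix whose
# center entry is the zero shift.
xcorr2_sum <- function(A, B) {
  nx <- nrow(A); ny <- ncol(A)
  px <- 2 * nx - 1; py <- 2 * ny - 1
  Ap <- matrix(0, px, py); Bp <- matrix(0, px, py)
  Ap[1:nx, 1:ny] <- A
  Bp[1:nx, 1:ny] <- B
  cc <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) /
    (px * py)
  # entry [dx mod px + 1, dy mod py + 1] holds shift (dx, dy); reorder to
  # dx = -(nx-1):(nx-1)
  ord_x <- c((px - nx + 2):px, 1:nx)
  ord_y <- c((py - ny + 2):py, 1:ny)
  cc[ord_x, ord_y]
}

#' Spatial autocorrelogram of a firing-rate map
#'
#' Pearson correlation of the (smoothed) map with itself at every integer
#' bin shift, computed over the overlapping visited bins only. Shifts with
#' fewer than `min_overlap` overlapping bins are `NA`. The central value is
#' 1 by construction and the autocorrelogram is symmetric under point
#' reflection through the origin.
#'
#' @param map A [compute_rate_map()] result (its smoothed `rate` is used).
#' @param min_overlap Minimum overlapping visited bins per shift.
#' @return Matrix of size `(2 nx - 1) x (2 ny - 1)` of correlations.
#' @export
spatial_autocorrelation <- function(map, min_overlap = 20) {
  M <- if (inherits(map, "rate_map")) map$rate else map
  W <- !is.na(M)
  if (sum(W) < 2) abort("need at least 2 visited bins")
  vals <- M[W]
  if (stats::sd(vals) == 0) abort("constant map: autocorrelation undefined")
  M0 <- ifelse(W, M, 0)
  Wn <- W + 0
  n <- round(xcorr2_sum(Wn, Wn))
  Sxy <- xcorr2_sum(M0, M0)
  Sx <- xcorr2_sum(M0, Wn)
  Sy <- xcorr2_sum(Wn, M0)
  Sxx <- xcorr2_sum(M0^2, Wn)
  Syy <- xcorr2_sum(Wn, M0^2)
  num <- n * Sxy - Sx * Sy
  den2 <- pmax(n * Sxx - Sx^2, 0) * pmax(n * Syy - Sy^2, 0)
  ac <- num / sqrt(den2)
  ac[n < min_overlap | den2 <= 1e-10] <- NA_real_
  ac <- pmin(pmax(ac, -1), 1)  # guard FFT round-off
  ac[nrow(M), ncol(M)] <- 1
  ac
}

# Bilinear interpolation of matrix values at fractional indices (NA outside
# or when any supporting bin is NA).
interp_bilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- rep(NA_real_, length(xi))
  if (!any(ok)) return(out)
  i0 <- x0[ok]; j0 <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
  v00 <- m[cbind(i0, j0)]; v10 <- m[cbind(i0 + 1, j0)]
  v01 <- m[cbind(i0, j0 + 1)]; v11 <- m[cbind(i0 + 1, j0 + 1)]
  out[ok] <- (1 - gx) * (1 - gy) * v00 + gx * (1 - gy) * v10 +
    (1 - gx) * gy * v01 + gx * gy * v11
  out
}

# Radial profile (mean over ~1-bin-wide annuli) of an autocorrelogram about
# its center.
radial_profile <- function(ac) {
  cx <- (nrow(ac) + 1) / 2; cy <- (ncol(ac) + 1) / 2
  ii <- row(ac) - cx; jj <- col(ac) - cy
  r <- sqrt(ii^2 + jj^2)
  rbin <- round(r)
  rmax <- max(rbin)
  vapply(0:rmax, function(k) mean(ac[rbin == k], na.rm = TRUE), numeric(1))
}

# Estimate the inner/outer radii of the hexagonal ring: inner = first local
# minimum of the radial profile after the central peak; outer = 1.5 x the
# radius of the next local maximum, capped at half the map extent. Falls
# back to [2, half extent] when no clear structure exists.
estimate_ring_radii <- function(ac) {
  prof <- radial_profile(ac)          # prof[k] = mean at radius k - 1
  nmap <- (nrow(ac) + 1) / 2          # original map extent (bins)
  half <- floor(nmap / 2)
  nmax <- length(prof)
  inner <- NA_real_; outer <- NA_real_
  ok <- function(k) k >= 1 && k <= nmax && !is.na(prof[k])
  for (k in 2:(nmax - 1)) {
    if (!ok(k - 1) || !ok(k) || !ok(k + 1)) next
    if (is.na(inner)) {
      if (prof[k] <= prof[k - 1] && prof[k] <= prof[k + 1]) inner <- k - 1
    } else if (prof[k] >= prof[k - 1] && prof[k] >= prof[k + 1]) {
      outer <- min((k - 1) * 1.5, half)
      break
    }
  }
  if (is.na(inner) || inner >= half) inner <- 2
  if (is.na(outer) || outer <= inner) outer <- half
  c(inner = inner, outer = outer)
}

# Correlation between the ring of the autocorrelogram and its copy rotated
# by `angle_deg` about the center (bilinear resampling).
ring_rotation_correlation <- function(ac, angle_deg, inner, outer) {
  cx <- (nrow(ac) + 1) / 2; cy <- (ncol(ac) + 1) / 2
  ii <- row(ac) - cx; jj <- col(ac) - cy
  r <- sqrt(ii^2 + jj^2)
  sel <- which(r >= inner & r <= outer)
  th <- deg2rad(angle_deg)
  xi <- cx + cos(th) * ii[sel] - sin(th) * jj[sel]
  yi <- cy + sin(th) * ii[sel] + cos(th) * jj[sel]
  a <- ac[sel]
  b <- interp_bilinear(ac, xi, yi)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 20) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

#' Grid score of a firing-rate map
#'
#' Rotational periodicity measure: the ring of the spatial autocorrelogram
#' containing the six nearest peaks is correlated with itself at 3-degree
#' rotational offsets from 0 to 180 degrees; the score is the lowest
#' correlation at 60 or 120 degrees minus the highest at 30, 90 or 150
#' degrees. Hexagonal maps score high (> 0.4 is the grid-cell criterion);
#' square lattices score negative.
#'
#' @inheritParams spatial_autocorrelation
#' @return List with `score`, `rotation_correlations` (tibble: angle_deg,
#'   correlation), `inner_radius`, `outer_radius` (bins). `score` is `NA`
#'   when the ring cannot be estimated.
#' @export
grid_score <- function(map, min_overlap = 20) {
  ac <- tryCatch(spatial_autocorrelation(map, min_overlap),
                 error = function(e) NULL)
  if (is.null(ac)) {
    return(list(score = NA_real_, rotation_correlations = tibble::tibble(),
                inner_radius = NA_real_, outer_radius = NA_real_))
  }
  radii <- estimate_ring_radii(ac)
  angles <- seq(0, 180, by = 3)
  cors <- vapply(angles, ring_rotation_correlation, numeric(1),
                 ac = ac, inner = radii["inner"], outer = radii["outer"])
  at <- function(a) cors[angles == a]
  score <- min(at(60), at(120)) - max(at(30), at(90), at(150))
  list(
    score = unname(score),
    rotation_correlations = tibble::tibble(angle_deg = angles, correlation = cors),
    inner_radius = unname(radii["inner"]), outer_radius = unname(radii["outer"])
  )
}

# 4-connected component labels of a logical matrix, deterministically
# numbered by smallest linear (column-major) index.
label_components <- function(mask) {
  n <- sum(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0) return(lab)
  idx <- which(mask)
  pos <- match(seq_len(length(mask)), idx)  # linear -> vertex id
  nr <- nrow(mask)
  edges <- integer(0)
  for (v in seq_along(idx)) {
    l <- idx[v]
    i <- (l - 1L) %% nr + 1L
    j <- (l - 1L) %/% nr + 1L
    if (i < nr && mask[l + 1L]) edges <- c(edges, v, pos[l + 1L])
    if (j < ncol(mask) && mask[l + nr]) edges <- c(edges, v, pos[l + nr])
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  relabel <- match(memb, unique(memb))  # unique() keeps first-seen order
  lab[idx] <- relabel
  lab
}

#' Detect firing fields in a rate map
#'
#' Thresholds the smoothed map at `threshold_pct` of its maximum and keeps
#' 4-connected components with area at least `min_area` cm^2. Centroids are
#' rate-weighted mean bin-center positions.
#'
#' @inheritParams spatial_autocorrelation
#' @param threshold_pct Threshold as percent of the maximum rate.
#' @param min_area Minimum field area (cm^2).
#' @return Tibble: `field_id`, `n_bins`, `area_cm2`, `centroid_x`,
#'   `centroid_y`, `peak_rate`; zero rows when no field qualifies.
#' @export
detect_fields <- function(map, threshold_pct = 30, min_area = 150) {
  stopifnot(inherits(map, "rate_map"))
  M <- map$rate
  mx <- max(M, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    return(tibble::tibble(field_id = integer(0), n_bins = integer(0),
                          area_cm2 = numeric(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), peak_rate = numeric(0)))
  }
  mask <- !is.na(M) & M >= threshold_pct / 100 * mx
  lab <- label_components(mask)
  bin_area <- map$bin_size^2
  keep <- which(tabulate(lab[lab > 0]) * bin_area >= min_area)
  purrr::map_dfr(seq_along(keep), function(k) {
    sel <- which(lab == keep[k])
    i <- (sel - 1L) %% nrow(M) + 1L
    j <- (sel - 1L) %/% nrow(M) + 1L
    w <- M[sel]
    tibble::tibble(
      field_id = k, n_bins = length(sel),
      area_cm2 = length(sel) * bin_area,
      centroid_x = sum(w * map$x_centers[i]) / sum(w),
      centroid_y = sum(w * map$y_centers[j]) / sum(w),
      peak_rate = max(w)
    )
  })
}

#' Border score of a firing-rate map
#'
#' Bins below 20% of the maximum rate are removed, firing fields are
#' 4-connected components of at least `min_area` cm^2, `c` is the maximum
#' fraction of any single wall's adjacent bin row covered by a single
#' field, and `d` is the rate-weighted mean distance of all field bins from
#' their nearest wall, normalized by half the wall length. The score is
#' `(c - d) / (c + d)`, in `[-1, 1]`.
#'
#' @inheritParams detect_fields
#' @return List with `score`, `c`, `d`, `n_fields`; `score` is `NA` when no
#'   field qualifies.
#' @export
border_score <- function(map, threshold_pct = 20, min_area = 200) {
  stopifnot(inherits(map, "rate_map"))
  M <- map$rate
  mx <- max(M, na.rm = TRUE)
  empty <- list(score = NA_real_, c = NA_real_, d = NA_real_, n_fields = 0L)
  if (!is.finite(mx) || mx <= 0) return(empty)
  mask <- !is.na(M) & M >= threshold_pct / 100 * mx
  lab <- label_components(mask)
  bin_area <- map$bin_size^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * bin_area >= min_area)
  if (length(keep) == 0) return(empty)
  lab[!(lab %in% keep)] <- 0L

  nx <- nrow(M); ny <- ncol(M)
  wall_rows <- list(
    south = cbind(seq_len(nx), 1L), north = cbind(seq_len(nx), ny),
    west = cbind(1L, seq_len(ny)), east = cbind(nx, seq_len(ny))
  )
  cmax <- 0
  for (wr in wall_rows) {
    labs_on_wall <- lab[wr]
    vis <- !is.na(M[wr])   # coverage judged over visited wall bins
    if (!any(vis)) next
    for (f in keep) {
      cmax <- max(cmax, mean(labs_on_wall[vis] == f))
    }
  }
  sel <- which(lab > 0)
  i <- (sel - 1L) %% nx + 1L
  j <- (sel - 1L) %/% nx + 1L
  xc <- map$x_centers[i]; yc <- map$y_centers[j]
  L <- map$side_length
  dist_wall <- pmin(xc, L - xc, yc, L - yc)
  w <- M[sel]
  d <- (sum(w * dist_wall) / sum(w)) / (L / 2)
  list(score = (cmax - d) / (cmax + d), c = cmax, d = d,
       n_fields = length(keep))
}

#' Spatial information content of a rate map (bits/spike)
#'
#' \eqn{SI = \sum_i P_i (R_i / R) \log_2(R_i / R)} over visited bins, with
#' `P_i` from the smoothed occupancy histogram, `R_i` the smoothed rate and
#' `R` the occupancy-weighted mean rate. Zero-rate bins contribute zero.
#' `SI >= 0`, with equality iff the map is uniform; it is invariant to
#' uniform rate rescaling.
#'
#' @inheritParams spatial_autocorrelation
#' @return Scalar bits/spike (`NA` when the mean rate is zero).
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  p <- map$occupancy_smoothed / sum(map$occupancy_smoothed, na.rm = TRUE)
  Ri <- map$rate
  R <- sum(p * Ri, na.rm = TRUE)
  if (!is.finite(R) || R <= 0) return(NA_real_)
  term <- p * (Ri / R) * log2(Ri / R)
  term[!is.na(Ri) & Ri == 0] <- 0
  sum(term, na.rm = TRUE)
}

#' Population mean of normalized rate maps with goal-zone comparison
#'
#' Each map is min-max rescaled to `[0, 1]` (optionally inverted, e.g. for
#' center-distance cells with negative slope), averaged element-wise, and
#' the mean value in the goal zone is compared against the three
#' rotationally equivalent zones. Constant maps cannot be rescaled and are
#' excluded.
#'
#' @param maps List of [compute_rate_map()] results with common geometry.
#' @param arena An [arena_geometry()].
#' @param invert Logical vector (one per map): rescale as `1 - map`.
#' @return List with `mean_map` (matrix), `n_used`, `zone_rates` (tibble of
#'   per-zone mean normalized rate).
#' @export
population_normalized_map <- function(maps, arena, invert = NULL) {
  stopifnot(length(maps) >= 1)
  invert <- invert %||% rep(FALSE, length(maps))
  acc <- cnt <- NULL
  used <- 0L
  for (k in seq_along(maps)) {
    M <- maps[[k]]$rate
    rng <- range(M, na.rm = TRUE)
    if (diff(rng) == 0) next
    Mn <- (M - rng[1]) / diff(rng)
    if (invert[k]) Mn <- 1 - Mn
    if (is.null(acc)) {
      acc <- matrix(0, nrow(Mn), ncol(Mn)); cnt <- acc
    }
    ok <- !is.na(Mn)
    acc[ok] <- acc[ok] + Mn[ok]
    cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  if (used == 0L) abort("no non-constant maps to average")
  mean_map <- ifelse(cnt > 0, acc / cnt, NA_real_)
  ref <- maps[[which(vapply(maps, function(m) {
    diff(range(m$rate, na.rm = TRUE)) > 0
  }, logical(1)))[1]]]
  grid <- expand.grid(i = seq_along(ref$x_centers), j = seq_along(ref$y_centers))
  gx <- ref$x_centers[grid$i]; gy <- ref$y_centers[grid$j]
  zones <- equivalent_zones(arena)
  labels <- equivalent_zone_labels(arena)
  zone_rates <- purrr::map2_dfr(zones, seq_along(zones), function(z, k) {
    inz <- in_zone(gx, gy, z)
    tibble::tibble(
      zone = labels[k], rotation_deg = (k - 1) * 90, is_goal = k == 1L,
      mean_rate = mean(mean_map[cbind(grid$i, grid$j)][inz], na.rm = TRUE)
    )
  })
  list(mean_map = mean_map, n_used = used, zone_rates = zone_rates)
}

#' Combined cell classification from GLM selection, scores and thresholds
#'
#' Applies the classification rules: grid iff GLM-location-significant and
#' grid score > 0.4; border iff GLM-location and border score > 0.5 (grid
#' takes precedence when both pass); non-grid spatial iff GLM-location,
#' spatial information above its within-cell shuffle threshold, and neither
#' grid nor border; HD iff GLM-HD, MVL above both its shuffle threshold and
#' an overall 0.2 floor, and peak rate > 1 Hz (reported as `lm_hd` for POR
#' cells); CB analogous on center bearing; CD iff GLM-distance, linear or
#' Gaussian R-squared above its shuffle threshold, and peak rate > 1 Hz.
#'
#' @param selected Character vector of GLM-selected variables (or a
#'   [forward_select()] result).
#' @param scores Named list: `grid_score`, `border_score`, `spatial_info`,
#'   `hd_mvl`, `hd_peak`, `cb_mvl`, `cb_peak`, `cd_linear_r2`,
#'   `cd_gaussian_r2`, `cd_peak`. Missing entries simply fail their rule.
#' @param thresholds Named list of within-cell shuffle thresholds:
#'   `spatial_info`, `hd_mvl`, `cb_mvl`, `cd_linear_r2`, `cd_gaussian_r2`.
#' @param region `"POR"` or `"MEC_PaS"` (controls the hd/lm_hd label).
#' @param grid_cut,border_cut,mvl_floor,peak_floor Fixed criterion values.
#' @return One-row tibble of logical flags (`grid`, `border`,
#'   `nongrid_spatial`, `hd`, `cb`, `cd`) plus a composite `label`.
#' @export
classify_cell <- function(selected, scores, thresholds, region = "MEC_PaS",
                          grid_cut = 0.4, border_cut = 0.5,
                          mvl_floor = 0.2, peak_floor = 1) {
  if (inherits(selected, "glm_selection")) selected <- selected$selected
  sc <- function(nm) {
    v <- scores[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  th <- function(nm) {
    v <- thresholds[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  pass <- function(x) !is.na(x) && x
  loc <- "location" %in% selected
  grid <- pass(loc && sc("grid_score") > grid_cut)
  border <- pass(loc && !grid && sc("border_score") > border_cut)
  nongrid <- pass(loc && !grid && !border &&
                    sc("spatial_info") > th("spatial_info"))
  hd <- pass("hd" %in% selected &&
               sc("hd_mvl") > th("hd_mvl") && sc("hd_mvl") > mvl_floor &&
               sc("hd_peak") > peak_floor)
  cb <- pass("center_bearing" %in% selected &&
               sc("cb_mvl") > th("cb_mvl") && sc("cb_mvl") > mvl_floor &&
               sc("cb_peak") > peak_floor)
  cd <- pass("center_distance" %in% selected &&
               (isTRUE(sc("cd_linear_r2") > th("cd_linear_r2")) ||
                  isTRUE(sc("cd_gaussian_r2") > th("cd_gaussian_r2"))) &&
               sc("cd_peak") > peak_floor)
  flags <- c(
    grid = grid, border = border, nongrid_spatial = nongrid,
    hd = hd, cb = cb, cd = cd
  )
  lab_names <- names(flags)
  lab_names[lab_names == "hd"] <- if (region == "POR") "lm_hd" else "hd"
  label <- paste(lab_names[flags], collapse = "+")
  tibble::tibble(
    grid = grid, border = border, nongrid_spatial = nongrid,
    hd = hd, cb = cb, cd = cd, region = region,
    label = if (label == "") "unclassified" else label
  )
}
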