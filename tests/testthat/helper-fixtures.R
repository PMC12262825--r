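# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (loops, closed forms, base-R summation) and
# independent of the package's vectorized/FFT implementations.

default_arena <- arena_geometry()

# Cache short synthetic sessions across test files (built once per run).
.fixture_env <- new.env()

fixture_tracking <- function(duration = 300, seed = 101, goal_bias = 0.5) {
  key <- paste0("tr_", duration, "_", seed, "_", goal_bias)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_trajectory(
      default_arena, sim_config(duration_s = duration, goal_bias = goal_bias),
      seed = seed
    )
  }
  .fixture_env[[key]]
}

# Hand-built tracking: constant frame rate, explicit positions/hd.
make_tracking <- function(x, y, hd = rep(0, length(x)), frame_rate = 30) {
  tibble::tibble(
    time_s = (seq_along(x) - 1) / frame_rate,
    x_cm = x, y_cm = y, hd_deg = hd
  )
}

# Minimal rate_map object from a rate matrix (uniform occupancy), for score
# functions that only need the smoothed map.
make_map <- function(rate, bin_size = 2.5, occupancy = NULL) {
  n <- nrow(rate)
  occ <- if (is.null(occupancy)) matrix(1, n, ncol(rate)) else occupancy
  occ[is.na(rate)] <- NA_real_
  p <- occ / sum(occ, na.rm = TRUE)
  structure(
    list(
      rate = rate, rate_raw = rate, counts = rate,
      occupancy = ifelse(is.na(occ), 0, occ), occupancy_smoothed = occ,
      bin_size = bin_size, smooth_sigma = 0,
      x_centers = (seq_len(n) - 0.5) * bin_size,
      y_centers = (seq_len(ncol(rate)) - 0.5) * bin_size,
      mean_rate = sum(p * rate, na.rm = TRUE),
      n_spikes = NA_integer_, dt = 1 / 30,
      side_length = n * bin_size
    ),
    class = "rate_map"
  )
}

# Three-cosine hexagonal lattice map (the canonical grid-cell construction).
hex_map <- function(n = 48, bin_size = 2.5, spacing = 40, orientation = 0) {
  centers <- (seq_len(n) - 0.5) * bin_size
  kmag <- 4 * pi / (sqrt(3) * spacing)
  g <- matrix(0, n, n)
  for (a in (orientation + c(0, 60, 120)) * pi / 180) {
    g <- g + outer(centers, centers, function(x, y) {
      cos(kmag * (cos(a) * x + sin(a) * y))
    })
  }
  (g + 1.5) / 4.5
}

square_lattice_map <- function(n = 48, bin_size = 2.5, spacing = 40) {
  centers <- (seq_len(n) - 0.5) * bin_size
  k <- 2 * pi / spacing
  (outer(centers, centers, function(x, y) cos(k * x) + cos(k * y)) + 2) / 4
}

gaussian_bump_map <- function(n = 48, bin_size = 2.5, center = c(60, 60),
                              width = 15) {
  centers <- (seq_len(n) - 0.5) * bin_size
  outer(centers, centers, function(x, y) {
    exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * width^2))
  })
}

# --- independent oracles -------------------------------------------------

# Brute-force Poisson log-likelihood via stats::dpois.
oracle_poisson_loglik <- function(n, r) sum(dpois(n, r, log = TRUE))

# Brute-force masked-Pearson autocorrelogram: explicit loop over shifts.
oracle_autocorr <- function(M, min_overlap = 20) {
  nx <- nrow(M); ny <- ncol(M)
  out <- matrix(NA_real_, 2 * nx - 1, 2 * ny - 1)
  for (dx in -(nx - 1):(nx - 1)) {
    for (dy in -(ny - 1):(ny - 1)) {
      a <- c(); b <- c()
      for (i in 1:nx) {
        for (j in 1:ny) {
          i2 <- i + dx; j2 <- j + dy
          if (i2 >= 1 && i2 <= nx && j2 >= 1 && j2 <= ny &&
              !is.na(M[i, j]) && !is.na(M[i2, j2])) {
            a <- c(a, M[i, j]); b <- c(b, M[i2, j2])
          }
        }
      }
      if (length(a) >= min_overlap && sd(a) > 0 && sd(b) > 0) {
        out[dx + nx, dy + ny] <- cor(a, b)
      }
    }
  }
  out
}

# Independent ring-rotation correlation: scalar loop with its own bilinear
# interpolation (the package resamples with vectorized index arithmetic).
oracle_ring_rotation <- function(ac, angle_deg, inner, outer) {
  cx <- (nrow(ac) + 1) / 2; cy <- (ncol(ac) + 1) / 2
  bilin <- function(xi, yi) {
    x0 <- floor(xi); y0 <- floor(yi)
    if (x0 < 1 || x0 + 1 > nrow(ac) || y0 < 1 || y0 + 1 > ncol(ac)) return(NA)
    fx <- xi - x0; fy <- yi - y0
    (1 - fx) * (1 - fy) * ac[x0, y0] + fx * (1 - fy) * ac[x0 + 1, y0] +
      (1 - fx) * fy * ac[x0, y0 + 1] + fx * fy * ac[x0 + 1, y0 + 1]
  }
  a <- c(); b <- c()
  th <- angle_deg * pi / 180
  for (i in seq_len(nrow(ac))) {
    for (j in seq_len(ncol(ac))) {
      r <- sqrt((i - cx)^2 + (j - cy)^2)
      if (r < inner || r > outer || is.na(ac[i, j])) next
      v <- bilin(cx + cos(th) * (i - cx) - sin(th) * (j - cy),
                 cy + sin(th) * (i - cx) + cos(th) * (j - cy))
      if (!is.na(v)) { a <- c(a, ac[i, j]); b <- c(b, v) }
    }
  }
  cor(a, b)
}

# MVL of a binned curve by direct complex summation.
oracle_mvl <- function(rates, centers_deg) {
  keep <- !is.na(rates)
  z <- sum(rates[keep] * exp(1i * centers_deg[keep] * pi / 180))
  Mod(z) / sum(rates[keep])
}

expect_wrapped_close <- function(a, b, tol) {
  expect_lt(abs(circ_diff(a, b)), tol)
}
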