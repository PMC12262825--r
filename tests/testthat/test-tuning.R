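test_that("rate map conserves spikes, handles the no-spike case, and keeps mean rate under smoothing", {
  tr <- fixture_tracking(duration = 300, seed = 101)
  m <- tuning_model("nongrid")
  sp <- generate_spikes(tr, m, default_arena, seed = 2)
  rm_ <- compute_rate_map(tr, sp, default_arena)
  expect_equal(sum(rm_$counts), length(sp))
  expect_equal(sum(rm_$occupancy), nrow(tr) / 30, tolerance = 1e-9)
  # unvisited bins are NA in raw and smoothed maps
  expect_true(all(is.na(rm_$rate[rm_$occupancy == 0])))

  rm0 <- compute_rate_map(tr, numeric(0), default_arena)
  expect_true(all(rm0$rate[!is.na(rm0$rate)] == 0))

  # uniform synthetic occupancy: smoothing preserves the mean rate
  n <- 48
  xx <- rep((seq_len(n) - 0.5) * 2.5, times = n)
  yy <- rep((seq_len(n) - 0.5) * 2.5, each = n)
  tru <- make_tracking(rep(xx, 4), rep(yy, 4))
  spu <- tru$time_s[seq(1, nrow(tru), by = 7)] + 0.001
  rmu <- compute_rate_map(tru, spu, default_arena)
  expect_equal(mean(rmu$rate), mean(rmu$rate_raw), tolerance = 0.01)
  # single spike in one frame of uniform occupancy: one nonzero raw bin
  rm1 <- compute_rate_map(tru, tru$time_s[10] + 0.001, default_arena)
  expect_equal(sum(rm1$rate_raw > 0), 1)
  expect_equal(max(rm1$rate_raw), 1 / rm1$occupancy[rm1$rate_raw > 0][1])
})

test_that("MVL of binned curves matches the complex-sum oracle and known limits", {
  centers <- (1:30 - 0.5) * 12
  # all mass in the bin at 0 degrees
  r1 <- c(5, rep(0, 29))
  mv <- curve_mvl(r1, centers)
  expect_equal(mv$mvl, 1)
  expect_equal(mv$preferred_deg, 6)   # first bin center
  # flat curve
  expect_equal(curve_mvl(rep(2, 30), centers)$mvl, 0, tolerance = 1e-12)
  # antipodal bins cancel
  r2 <- rep(0, 30); r2[1] <- 3; r2[16] <- 3
  expect_equal(curve_mvl(r2, centers)$mvl, 0, tolerance = 1e-12)
  # random curve vs brute-force complex sum
  set.seed(1)
  for (i in 1:5) {
    rr <- runif(30)
    expect_equal(curve_mvl(rr, centers)$mvl, oracle_mvl(rr, centers),
                 tolerance = 1e-12)
  }
})

test_that("circular tuning curve bins occupancy and spikes correctly", {
  # stationary animal sweeping hd uniformly: flat occupancy
  tr <- make_tracking(rep(60, 3600), rep(60, 3600), hd = rep(0:359, 10))
  cv <- circular_tuning_curve(tr, numeric(0))
  expect_equal(nrow(cv), 30)
  expect_true(all(abs(cv$occupancy_s - 4) < 1e-9))
  # spikes only while facing ~90 degrees
  sp <- tr$time_s[tr$hd_deg == 90] + 0.001
  cv2 <- circular_tuning_curve(tr, sp)
  expect_equal(which(cv2$rate_hz > 0), 8)   # bin covering [84, 96)
  expect_equal(mvl(cv2), 1)
})

test_that("distance tuning fits recover linear and Gaussian profiles", {
  # engineered frames at controlled distances: ring sweep
  angs <- runif(20000, 0, 2 * pi)
  rad <- sqrt(runif(20000)) * 59
  tr <- make_tracking(60 + rad * cos(angs), 60 + rad * sin(angs))
  d <- sqrt((tr$x_cm - 60)^2 + (tr$y_cm - 60)^2)

  # noiseless linear rate = 2 + 0.1 d: spike counts proportional per frame
  lam <- (2 + 0.1 * d) / 30
  set.seed(5)
  counts <- rpois(length(lam), lam * 50)   # dense spikes, low noise
  sp <- rep(tr$time_s, counts) + 0.001
  cv <- distance_tuning_curve(tr, sp, default_arena)
  expect_gt(attr(cv, "linear_r2"), 0.98)
  expect_gt(attr(cv, "linear_slope"), 0)

  # exactly constant rate (one spike per frame): no variance to explain
  cvc <- distance_tuning_curve(tr, tr$time_s + 0.001, default_arena)
  expect_equal(attr(cvc, "linear_r2"), 0)

  # noiseless Gaussian bump, center 30 cm, width 10 cm
  lam_g <- exp(-(d - 30)^2 / (2 * 10^2))
  counts_g <- rpois(length(lam_g), lam_g * 3)
  sp_g <- rep(tr$time_s, counts_g) + 0.001
  cvg <- distance_tuning_curve(tr, sp_g, default_arena)
  expect_gt(attr(cvg, "gaussian_r2"), 0.95)
  expect_lt(abs(attr(cvg, "gaussian_pars")$m - 30), 2)
})

test_that("spike-train shuffling wraps, preserves counts and intervals", {
  expect_equal(shuffle_spike_train(c(5), 1200, shift = 30), 35)
  expect_equal(shuffle_spike_train(c(1195), 1200, shift = 30), 25)
  expect_equal(shuffle_spike_train(c(1, 2, 3), 1200, shift = 1200), c(1, 2, 3))
  sp <- sort(runif(200, 0, 1200))
  sh <- shuffle_spike_train(sp, 1200, seed = 3)
  expect_length(sh, 200)
  # inter-spike intervals preserved modulo one wrap point
  isi <- function(x) sort(round(diff(x), 9))
  expect_gte(sum(isi(sh) %in% isi(sp)), 197)
  expect_error(shuffle_spike_train(sp, 50, min_shift = 30), "exceed")
})

test_that("shuffle threshold equals the constant for a constant statistic", {
  sp <- sort(runif(100, 0, 600))
  th <- shuffle_threshold(sp, 600, function(s) 7.5, n_shuffles = 50, seed = 1)
  expect_equal(th$threshold, 7.5)
  expect_error(
    shuffle_threshold(sp, 600, function(s) NA_real_, n_shuffles = 20, seed = 1),
    "undefined"
  )
})

test_that("fast shuffle-threshold paths equal the generic implementation", {
  tr <- fixture_tracking(duration = 300, seed = 101)
  sp <- generate_spikes(tr, tuning_model("hd", peak_rate = 8),
                        default_arena, seed = 4)
  generic_mvl <- shuffle_threshold(
    sp, 300, function(s) mvl(circular_tuning_curve(tr, s)),
    n_shuffles = 40, seed = 17
  )$threshold
  fast_mvl <- openfieldr:::shuffle_threshold_curve_mvl(
    tr, sp, n_shuffles = 40, seed = 17
  )
  expect_equal(fast_mvl, generic_mvl, tolerance = 1e-12)

  generic_si <- shuffle_threshold(
    sp, 300,
    function(s) spatial_information(compute_rate_map(tr, s, default_arena)),
    n_shuffles = 40, seed = 18
  )$threshold
  fast_si <- openfieldr:::shuffle_threshold_si(
    tr, sp, default_arena, n_shuffles = 40, seed = 18
  )
  expect_equal(fast_si, generic_si, tolerance = 1e-10)
})

test_that("occupancy resampling flattens the coarse occupancy map", {
  tr <- fixture_tracking(duration = 300, seed = 101)
  m <- tuning_model("hd", peak_rate = 8)
  sp <- generate_spikes(tr, m, default_arena, seed = 4)
  rs <- resample_equal_occupancy(tr, sp, default_arena, seed = 2)
  bx <- pmin(floor(rs$tracking$x_cm / 15), 7)
  by <- pmin(floor(rs$tracking$y_cm / 15), 7)
  counts <- table(bx * 8 + by)
  expect_lt(max(counts) - min(counts), 1 + 1e-9)  # flat across visited bins
  # never increases occupancy, spikes only from retained frames
  expect_lte(nrow(rs$tracking), nrow(tr))
  expect_true(all(rs$spikes %in% sp))
  # already-equal occupancy: output is the input
  n <- 48
  xx <- rep((seq_len(8) - 0.5) * 15, times = 8)
  yy <- rep((seq_len(8) - 0.5) * 15, each = 8)
  tru <- make_tracking(rep(xx, 3), rep(yy, 3))
  rs2 <- resample_equal_occupancy(tru, numeric(0), default_arena, seed = 1)
  expect_equal(sort(rs2$tracking$time_s), tru$time_s)
})
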