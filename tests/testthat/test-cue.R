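test_that("bidirectionality index hits its closed-form limits", {
  centers <- (1:30 - 0.5) * 12
  # symmetric bimodal curve: MVL_normal = 0 so BI = 1
  r_bi <- exp(2 * (cos((centers - 40) * pi / 180) - 1)) +
    exp(2 * (cos((centers - 220) * pi / 180) - 1))
  m_n <- curve_mvl(r_bi, centers)$mvl
  r_bi_doubled <- (exp(2 * (cos((centers / 2 - 40) * pi / 180) - 1)) +
                     exp(2 * (cos((centers / 2 - 220) * pi / 180) - 1)) +
                     exp(2 * (cos((centers / 2 + 180 - 40) * pi / 180) - 1)) +
                     exp(2 * (cos((centers / 2 + 180 - 220) * pi / 180) - 1))) / 2
  m_d <- curve_mvl(r_bi_doubled, centers)$mvl
  expect_lt(m_n, 1e-10)
  expect_equal((m_d - m_n) / (m_d + m_n), 1, tolerance = 1e-8)

  # unimodal von Mises kappa = 2: BI from the Bessel-moment oracle
  r_uni <- exp(2 * (cos((centers - 90) * pi / 180) - 1))
  mvl_normal <- curve_mvl(r_uni, centers)$mvl
  r_uni_doubled <- (exp(2 * (cos((centers / 2 - 90) * pi / 180) - 1)) +
                      exp(2 * (cos((centers / 2 + 180 - 90) * pi / 180) - 1))) / 2
  mvl_doubled <- curve_mvl(r_uni_doubled, centers)$mvl
  bi <- (mvl_doubled - mvl_normal) / (mvl_doubled + mvl_normal)
  # the doubled-angle MVL of a von Mises curve is its second circular moment
  # I2(k)/I0(k); at k = 2 the Bessel oracle gives BI = -0.3956
  oracle_bi <- (besselI(2, 2) / besselI(2, 0) - besselI(2, 1) / besselI(2, 0)) /
    (besselI(2, 2) / besselI(2, 0) + besselI(2, 1) / besselI(2, 0))
  expect_equal(bi, oracle_bi, tolerance = 0.005)
  expect_equal(oracle_bi, -0.3956, tolerance = 0.0005)
})

test_that("bidirectionality index from spike data is scale-invariant and detects lobes", {
  tr <- make_tracking(rep(60, 7200), rep(60, 7200), hd = rep(0:359, 20))
  lam_bi <- 5 * (exp(4 * (cos((tr$hd_deg - 30) * pi / 180) - 1)) +
                   exp(4 * (cos((tr$hd_deg - 210) * pi / 180) - 1)))
  set.seed(4)
  sp_bi <- rep(tr$time_s, rpois(7200, lam_bi / 30)) + 1e-4
  b <- bidirectionality_index(tr, sp_bi)
  expect_gt(b$bi, 0.8)
  lam_uni <- 10 * exp(4 * (cos((tr$hd_deg - 30) * pi / 180) - 1))
  sp_uni <- rep(tr$time_s, rpois(7200, lam_uni / 30)) + 1e-4
  b2 <- bidirectionality_index(tr, sp_uni)
  expect_lt(b2$bi, -0.2)
})

test_that("bidirectional von Mises fit recovers constructed lobes", {
  tr <- make_tracking(rep(60, 3600), rep(60, 3600), hd = rep(0:359, 10))
  curve <- circular_tuning_curve(tr, numeric(0))
  # noiseless equal lobes at 45 and 225
  rate <- 2 + 6 * exp(3 * (cos((curve$bin_center_deg - 45) * pi / 180) - 1)) +
    6 * exp(3 * (cos((curve$bin_center_deg - 225) * pi / 180) - 1))
  cv <- curve
  cv$rate_hz <- rate
  fit <- fit_bidirectional_von_mises(cv, mode = "peak")
  expect_lt(abs(circ_diff(fit$mu_deg * 2, 90)) / 2, 2)  # mu within 2 deg mod 180
  expect_gt(fit$r_squared, 0.999)
  expect_gte(fit$max_fit, fit$min_fit)

  # flat curve: amplitudes collapse toward zero
  cvf <- curve; cvf$rate_hz <- rep(5, 30)
  fitf <- fit_bidirectional_von_mises(cvf, mode = "peak")
  expect_lt(max(fitf$amplitudes), 0.01 * fitf$offset + 1e-6)

  # trough fit mirrors the peak fit of the inverted curve
  cvt <- curve
  cvt$rate_hz <- 8 - 5 * exp(2 * (cos((curve$bin_center_deg - 100) * pi / 180) - 1))
  fit_t <- fit_bidirectional_von_mises(cvt, mode = "trough")
  inv <- cvt; inv$rate_hz <- max(cvt$rate_hz) - cvt$rate_hz
  fit_p <- fit_bidirectional_von_mises(inv, mode = "peak")
  expect_lt(abs(circ_diff(fit_t$mu_deg * 2, fit_p$mu_deg * 2)) / 2, 2)
  expect_equal(max(cvt$rate_hz) - fit_t$min_fit, fit_p$max_fit, tolerance = 0.05)
})

test_that("cue modulation indices follow the lobe-assignment and formulas", {
  tr <- make_tracking(rep(60, 3600), rep(60, 3600), hd = rep(0:359, 10))
  curve <- circular_tuning_curve(tr, numeric(0))
  # symmetric fit: equal lobes -> equal indices
  cv <- curve
  cv$rate_hz <- 1 + 4 * exp(3 * (cos((curve$bin_center_deg) * pi / 180) - 1)) +
    4 * exp(3 * (cos((curve$bin_center_deg - 180) * pi / 180) - 1))
  fit <- fit_bidirectional_von_mises(cv, mode = "peak")
  mi <- cue_modulation_indices(fit, 10)
  expect_equal(mi$mi_south, mi$mi_north, tolerance = 0.02)
  expect_lt(abs(circ_diff(mi$south_lobe_deg, 0)), 3)

  # purely unidirectional, zero offset: MI_S = 1, MI_N = 0
  cv2 <- curve
  cv2$rate_hz <- 5 * exp(4 * (cos((curve$bin_center_deg - 90) * pi / 180) - 1))
  fit2 <- fit_bidirectional_von_mises(cv2, mode = "peak")
  mi2 <- cue_modulation_indices(fit2, 90)
  expect_equal(mi2$mi_south, 1, tolerance = 0.05)
  expect_equal(mi2$mi_north, 0, tolerance = 0.05)
  expect_true(mi2$mi_south >= 0 && mi2$mi_south <= 1.001)
})

test_that("preferred-direction shifts are signed circular differences", {
  tr <- make_tracking(rep(60, 3600), rep(60, 3600), hd = rep(0:359, 10))
  mk <- function(mu) {
    lam <- 10 * exp(4 * (cos((tr$hd_deg - mu) * pi / 180) - 1))
    set.seed(round(mu) + 1)
    sp <- rep(tr$time_s, rpois(3600, lam / 30)) + 1e-4
    circular_tuning_curve(tr, sp)
  }
  c0 <- mk(40)
  expect_equal(preferred_direction_shift(c0, c0), 0)
  expect_equal(preferred_direction_shift(c0, mk(130)), 90, tolerance = 4)
  # 270-degree rotation reported as -90
  expect_equal(preferred_direction_shift(c0, mk(310)), -90, tolerance = 4)
})

test_that("rotated map correlations identify exact 90-degree copies", {
  M <- gaussian_bump_map(48, center = c(30, 80), width = 10) +
    0.4 * gaussian_bump_map(48, center = c(90, 30), width = 14)
  m1 <- make_map(M)
  expect_equal(rotated_map_correlations(m1, m1)$correlation[1], 1)
  rotM <- openfieldr:::rot90_ccw(M)
  rc <- rotated_map_correlations(make_map(rotM), m1)
  expect_equal(rc$correlation[rc$rotation_deg == 90], 1, tolerance = 1e-12)
  # isotropic map: all four correlations equal
  iso <- gaussian_bump_map(48, center = c(60, 60), width = 15)
  rci <- rotated_map_correlations(make_map(iso), make_map(iso))
  expect_lt(diff(range(rci$correlation)), 1e-9)
})

test_that("Rayleigh and V tests behave on reference cases", {
  expect_equal(rayleigh_test(rep(77, 10))$r, 1)
  expect_lt(rayleigh_test(rep(c(0, 90, 180, 270), 25))$r, 1e-12)
  expect_error(rayleigh_test(c(10)), "at least 2")
  # 100 von Mises kappa = 1 samples: r near I1(1)/I0(1) = 0.446
  set.seed(12)
  draws <- replicate(30, {
    ang <- openfieldr:::rvonmises(100, mu = pi / 3, kappa = 1) * 180 / pi
    rayleigh_test(ang)$r
  })
  expect_lt(abs(mean(draws) - besselI(1, 1) / besselI(1, 0)),
            3 * sd(draws) / sqrt(30))
  # concentrated sample: tiny P; uniform sample: large P
  set.seed(3)
  conc <- openfieldr:::rvonmises(50, 0, 8) * 180 / pi
  expect_lt(rayleigh_test(conc)$p_value, 1e-6)
  expect_gt(rayleigh_test(runif(50, 0, 360))$p_value, 0.05)
  # V test is sensitive to the predicted direction
  v_right <- v_test(conc, 0)
  v_wrong <- v_test(conc, 180)
  expect_lt(v_right$p_value, 0.001)
  expect_gt(v_wrong$p_value, 0.5)
})
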