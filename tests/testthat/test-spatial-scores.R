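test_that("spatial autocorrelation matches the brute-force masked-Pearson oracle", {
  set.seed(3)
  M <- matrix(runif(12 * 12), 12, 12)
  M[sample(144, 20)] <- NA   # unvisited bins
  ac <- spatial_autocorrelation(make_map(M), min_overlap = 20)
  expect_equal(dim(ac), c(23, 23))
  expect_equal(ac[12, 12], 1)
  oracle <- oracle_autocorr(M, min_overlap = 20)
  ok <- !is.na(oracle) & !is.na(ac)
  expect_equal(is.na(ac), is.na(oracle))
  expect_lt(max(abs(ac[ok] - oracle[ok])), 1e-8)
  # point symmetry through the origin
  expect_equal(ac, ac[23:1, 23:1])
})

test_that("autocorrelogram of an isotropic bump is isotropic; constant maps error", {
  M <- gaussian_bump_map(25, bin_size = 2.5, center = c(31.25, 31.25), width = 10)
  ac <- spatial_autocorrelation(make_map(M))
  c0 <- (nrow(ac) + 1) / 2
  # compare values at equal radii along the two axes
  for (r in c(3, 6, 9)) {
    vals <- c(ac[c0 + r, c0], ac[c0 - r, c0], ac[c0, c0 + r], ac[c0, c0 - r])
    expect_lt(diff(range(vals)), 1e-6)
  }
  expect_error(spatial_autocorrelation(make_map(matrix(1, 10, 10))), "constant")
})

test_that("ring rotation correlations match an independent scalar implementation", {
  M <- hex_map(36, spacing = 40)
  ac <- spatial_autocorrelation(make_map(M))
  radii <- openfieldr:::estimate_ring_radii(ac)
  for (ang in c(30, 60, 90)) {
    a <- openfieldr:::ring_rotation_correlation(ac, ang, radii["inner"],
                                                radii["outer"])
    b <- oracle_ring_rotation(ac, ang, radii["inner"], radii["outer"])
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("grid score separates hexagonal, square and single-bump maps", {
  gs_hex <- grid_score(make_map(hex_map(48, spacing = 40)))
  expect_gt(gs_hex$score, 0.4)
  gs_sq <- grid_score(make_map(square_lattice_map(48, spacing = 40)))
  expect_lt(gs_sq$score, 0)
  gs_bump <- grid_score(make_map(gaussian_bump_map(48, center = c(60, 60),
                                                   width = 20)))
  expect_lt(abs(gs_bump$score), 0.1)
  # rotating the hexagonal construction by 60 degrees leaves the score
  gs_hex60 <- grid_score(make_map(hex_map(48, spacing = 40, orientation = 60)))
  expect_lt(abs(gs_hex$score - gs_hex60$score), 0.05)
})

test_that("border score reproduces the hand-derived full-wall value and edge cases", {
  # one-bin-deep field spanning the whole south wall
  M <- matrix(0, 48, 48)
  M[, 1] <- 1
  bs <- border_score(make_map(M))
  expect_equal(bs$c, 1)
  expect_equal(bs$d, 1.25 / 60, tolerance = 1e-12)
  expect_equal(bs$score, (1 - 1.25 / 60) / (1 + 1.25 / 60), tolerance = 1e-12)
  expect_equal(bs$score, 0.959, tolerance = 1e-3)

  # central field touching no wall: c = 0 so score = -1
  Mc <- gaussian_bump_map(48, center = c(60, 60), width = 10)
  Mc[Mc < 0.19] <- 0
  bsc <- border_score(make_map(Mc))
  expect_equal(bsc$c, 0)
  expect_equal(bsc$score, -1)

  # no qualifying field -> missing score
  Mn <- matrix(0, 48, 48); Mn[5, 5] <- 1
  expect_true(is.na(border_score(make_map(Mn))$score))
  # always within [-1, 1]
  expect_true(bs$score >= -1 && bs$score <= 1)
})

test_that("spatial information matches the 4-bin worked example and its invariances", {
  # 4 equally occupied bins, firing in exactly one
  M <- matrix(c(8, 0, 0, 0), 2, 2)
  expect_equal(spatial_information(make_map(M)), 2.0, tolerance = 1e-12)
  # uniform map: zero information
  expect_equal(spatial_information(make_map(matrix(3, 6, 6))), 0,
               tolerance = 1e-12)
  # invariant to rate scaling; non-negative on random maps
  set.seed(9)
  R <- matrix(rexp(64), 8, 8)
  si1 <- spatial_information(make_map(R))
  expect_equal(si1, spatial_information(make_map(R * 7.3)), tolerance = 1e-12)
  expect_gte(si1, 0)
})

test_that("field detection finds connected supra-threshold components above the area floor", {
  M <- gaussian_bump_map(48, center = c(60, 60), width = 10)
  f <- detect_fields(make_map(M))
  expect_equal(nrow(f), 1)
  expect_lt(abs(f$centroid_x - 60), 2.5)
  expect_lt(abs(f$centroid_y - 60), 2.5)

  # uniform map: a single field covering everything, centroid at the center
  fu <- detect_fields(make_map(matrix(1, 48, 48)))
  expect_equal(nrow(fu), 1)
  expect_equal(fu$n_bins, 48 * 48)
  expect_equal(fu$centroid_x, 60)

  # two bumps of ~100 cm^2 each: below the 150 cm^2 minimum
  Ms <- matrix(0, 48, 48)
  Ms[4:7, 4:7] <- 1     # 16 bins = 100 cm^2
  Ms[30:33, 30:33] <- 1
  expect_equal(nrow(detect_fields(make_map(Ms), min_area = 150)), 0)
  expect_equal(nrow(detect_fields(make_map(Ms), min_area = 100)), 2)
})

test_that("population normalized maps average, invert and compare zones", {
  M <- gaussian_bump_map(48, center = c(35, 75), width = 12)
  maps <- list(make_map(M), make_map(M * 4 + 1))   # same shape, rescaled
  pop <- population_normalized_map(maps, default_arena)
  expect_equal(pop$n_used, 2)
  rng <- range(M)
  expect_equal(pop$mean_map, (M - rng[1]) / diff(rng), tolerance = 1e-9)
  # a map and its complement average to 0.5
  pop2 <- population_normalized_map(list(make_map(M), make_map(M)),
                                    default_arena, invert = c(FALSE, TRUE))
  expect_true(all(abs(pop2$mean_map - 0.5) < 1e-9))
  expect_equal(nrow(pop$zone_rates), 4)
  expect_gt(pop$zone_rates$mean_rate[pop$zone_rates$is_goal],
            max(pop$zone_rates$mean_rate[!pop$zone_rates$is_goal]))
})

test_that("classification rules follow thresholds, precedence and region labels", {
  thr <- list(spatial_info = 0.3, hd_mvl = 0.1, cb_mvl = 0.1,
              cd_linear_r2 = 0.4, cd_gaussian_r2 = 0.85)
  base <- list(grid_score = NA, border_score = NA, spatial_info = NA,
               hd_mvl = NA, hd_peak = NA, cb_mvl = NA, cb_peak = NA,
               cd_linear_r2 = NA, cd_gaussian_r2 = NA, cd_peak = NA)
  # grid cell passing both grid and border: grid precedence
  s <- utils::modifyList(base, list(grid_score = 0.5, border_score = 0.8))
  cl <- classify_cell("location", s, thr)
  expect_true(cl$grid); expect_false(cl$border)
  expect_equal(cl$label, "grid")
  # grid score 0.5 with GLM location -> grid
  expect_true(classify_cell("location",
                            utils::modifyList(base, list(grid_score = 0.5)),
                            thr)$grid)
  # HD MVL above shuffle threshold but under the 0.2 floor -> not HD
  s2 <- utils::modifyList(base, list(hd_mvl = 0.15, hd_peak = 5))
  expect_false(classify_cell("hd", s2, thr)$hd)
  # passing HD cell labeled lm_hd in POR
  s3 <- utils::modifyList(base, list(hd_mvl = 0.5, hd_peak = 5))
  expect_equal(classify_cell("hd", s3, thr, region = "POR")$label, "lm_hd")
  expect_equal(classify_cell("hd", s3, thr, region = "MEC_PaS")$label, "hd")
  # non-grid spatial requires failing grid and border
  s4 <- utils::modifyList(base, list(grid_score = 0.1, border_score = 0.2,
                                     spatial_info = 0.9))
  cl4 <- classify_cell("location", s4, thr)
  expect_true(cl4$nongrid_spatial)
  # no GLM support -> unclassified regardless of scores
  expect_equal(classify_cell(character(0), s4, thr)$label, "unclassified")
  # CD: either fit may clear its own shuffle threshold, peak rate required
  s5 <- utils::modifyList(base, list(cd_linear_r2 = 0.1, cd_gaussian_r2 = 0.9,
                                     cd_peak = 3))
  expect_true(classify_cell("center_distance", s5, thr)$cd)
  s5b <- utils::modifyList(s5, list(cd_gaussian_r2 = 0.5))
  expect_false(classify_cell("center_distance", s5b, thr)$cd)
  s6 <- utils::modifyList(s5, list(cd_peak = 0.5))
  expect_false(classify_cell("center_distance", s6, thr)$cd)
})
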