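test_that("poisson_loglik matches hand values and the dpois oracle", {
  expect_equal(poisson_loglik(c(1, 0), c(1, 1)), -2)
  set.seed(2)
  n <- rpois(50, 3)
  r <- runif(50, 0.5, 6)
  expect_equal(poisson_loglik(n, r), oracle_poisson_loglik(n, r),
               tolerance = 1e-10)
  # n = r is the per-bin maximum over r
  nn <- pmax(n, 1)
  expect_gte(poisson_loglik(nn, nn), poisson_loglik(nn, nn * 1.1))
  expect_gte(poisson_loglik(nn, nn), poisson_loglik(nn, nn * 0.9))
  expect_error(poisson_loglik(c(1), c(0)), "positive")
})

test_that("design matrix assigns one bin per variable per frame", {
  tr <- fixture_tracking(duration = 120, seed = 101)
  sp <- generate_spikes(tr, tuning_model("hd"), default_arena, seed = 1)
  d <- build_design(tr, sp, default_arena)
  expect_equal(dim(d$idx), c(nrow(tr), 5))
  expect_true(all(d$idx >= 1))
  expect_true(all(t(d$idx) <= d$nbins))
  expect_equal(sum(d$n), length(sp))
  # stationary animal: one location bin throughout
  trs <- make_tracking(rep(10, 200), rep(10, 200))
  ds <- build_design(trs, numeric(0), default_arena)
  expect_equal(length(unique(ds$idx[, "location"])), 1)
  # arena center falls in the first center-distance bin
  trc <- make_tracking(rep(60, 200), rep(60, 200))
  dc <- build_design(trc, numeric(0), default_arena)
  expect_equal(unique(dc$idx[, "center_distance"]), 1L)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  T_ <- 200
  nbins <- c(location = 16, hd = 6, center_bearing = 6,
             center_distance = 4, speed = 4)
  idx <- sapply(nbins, function(nb) sample.int(nb, T_, replace = TRUE))
  design <- structure(list(idx = idx, nbins = nbins, n_loc_side = 4,
                           n = rpois(T_, 0.3), dt = 1 / 30, n_frames = T_,
                           n_spikes = 0L),
                      class = "glm_design")
  vars <- colnames(idx)
  offsets <- c(0L, cumsum(nbins))[seq_along(nbins)]
  Q <- matrix(0, sum(nbins), sum(nbins))
  for (v in seq_along(vars)) {
    rng <- (offsets[v] + 1):(offsets[v] + nbins[v])
    S <- if (vars[v] == "location") 2 else 20
    Q[rng, rng] <- S * openfieldr:::penalty_laplacian(vars[v], nbins[v], 4)
  }
  # independent objective: plain R summation
  obj <- function(beta) {
    eta <- rowSums(sapply(seq_along(vars), function(v) {
      beta[offsets[v] + idx[, v]]
    }))
    sum(exp(eta) - design$n * eta) + 0.5 * sum(beta * (Q %*% beta))
  }
  beta <- rnorm(sum(nbins), 0, 0.3)
  g_analytic <- openfieldr:::glm_nll_grad(beta, idx, design$n, offsets)$grad +
    as.numeric(Q %*% beta)
  h <- 1e-5
  pick <- sample.int(length(beta), 25)
  g_fd <- vapply(pick, function(j) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    (obj(bp) - obj(bm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_analytic[pick] - g_fd) / pmax(abs(g_fd), 1e-3)), 1e-5)
})

test_that("penalized fit recovers HD tuning and flattens under huge smoothing", {
  tr <- fixture_tracking(duration = 600, seed = 77)
  m <- tuning_model("hd", preferred_deg = 90, kappa = 4,
                    baseline_rate = 0.5, peak_rate = 10)
  sp <- generate_spikes(tr, m, default_arena, seed = 8)
  d <- build_design(tr, sp, default_arena)
  f <- fit_glm(d, variables = "hd")
  expect_true(f$converged)
  gen <- 0.5 + 9.5 * exp(4 * (cos(((1:30 - 0.5) * 12 - 90) * pi / 180) - 1))
  expect_gt(cor(exp(f$beta$hd), gen), 0.9)
  # huge smoothing drives the parameter vector to a near-constant
  f_big <- fit_glm(d, variables = "hd", S = c(hd = 1e7))
  expect_lt(diff(range(f_big$beta$hd)), 0.01)
  # constant-rate cell: the penalty keeps the fitted HD curve nearly flat,
  # and flatter than the raw binned curve
  trc <- fixture_tracking(duration = 1200, seed = 11)
  spc <- generate_spikes(trc, tuning_model("hd", baseline_rate = 4,
                                           peak_rate = 4),
                         default_arena, seed = 9)
  dc <- build_design(trc, spc, default_arena)
  fc <- fit_glm(dc, variables = "hd")
  fitted_rel_range <- diff(range(exp(fc$beta$hd))) / mean(exp(fc$beta$hd))
  # Poisson noise alone gives ~8% per-bin SD at this spike count; the fit
  # must stay within that noise floor and be smoother than the raw curve
  expect_lt(fitted_rel_range, 0.4)
  raw <- circular_tuning_curve(trc, spc)
  raw_rel_range <- diff(range(raw$rate_hz)) / mean(raw$rate_hz)
  expect_lt(fitted_rel_range, raw_rel_range)
})

test_that("training likelihood never decreases when a variable is added", {
  tr <- fixture_tracking(duration = 300, seed = 101)
  sp <- generate_spikes(tr, tuning_model("hd", peak_rate = 10),
                        default_arena, seed = 3)
  d <- build_design(tr, sp, default_arena)
  f1 <- fit_glm(d, variables = "hd", S = c(hd = 0.1))
  f2 <- fit_glm(d, variables = c("hd", "center_distance"),
                S = c(hd = 0.1, center_distance = 0.1))
  expect_gte(f2$loglik, f1$loglik - 1e-3)
})

test_that("forward selection recovers an HD cell and leaves a null unclassified", {
  tr <- fixture_tracking(duration = 600, seed = 77)
  sp <- generate_spikes(tr, tuning_model("hd", preferred_deg = 200, kappa = 4,
                                         peak_rate = 10),
                        default_arena, seed = 21)
  sel <- forward_select(build_design(tr, sp, default_arena))
  expect_true("hd" %in% sel$selected)

  sp0 <- generate_spikes(tr, tuning_model("hd", baseline_rate = 3,
                                          peak_rate = 3),
                         default_arena, seed = 22)
  sel0 <- forward_select(build_design(tr, sp0, default_arena))
  expect_length(sel0$selected, 0)
  expect_false(sel0$classified)

  # too few spikes -> unclassified with reason
  sel_few <- forward_select(build_design(tr, sp[1:20], default_arena))
  expect_false(sel_few$classified)
  expect_match(sel_few$reason, "spikes")
  expect_error(forward_select(build_design(tr, sp, default_arena), k = 1),
               "k must be")
})

test_that("tidiers expose per-fold log-likelihoods and a one-row summary", {
  tr <- fixture_tracking(duration = 300, seed = 101)
  sp <- generate_spikes(tr, tuning_model("hd", peak_rate = 10),
                        default_arena, seed = 3)
  sel <- forward_select(build_design(tr, sp, default_arena))
  td <- tidy(sel)
  expect_true(all(c("fold", "subset", "loglik") %in% names(td)))
  expect_equal(length(unique(td$fold)), 10)
  expect_equal(sum(td$subset == "(mean rate)"), 10)
  gl <- glance(sel)
  expect_equal(nrow(gl), 1)
  expect_true(is.character(gl$selected))
})
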