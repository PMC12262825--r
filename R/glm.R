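#' @useDynLib openfieldr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

glm_variables <- c("location", "hd", "center_bearing", "center_distance", "speed")

default_smoothing <- function() {
  c(location = 2, hd = 20, center_bearing = 20, center_distance = 20, speed = 20)
}

#' Build the one-hot design for the Poisson encoding model
#'
#' Discretizes the animal's state at every frame into one active bin per
#' behavioral variable: 2D location (20 x 20 = 400 bins), allocentric head
#' direction (30 bins), egocentric bearing of the arena center (30 bins),
#' distance from the arena center (10 bins over `[0, side/sqrt(2)]`), and
#' linear speed (10 bins; displacement per frame smoothed over a short
#' running window). Frame spike counts are attached as the response.
#'
#' @inheritParams compute_rate_map
#' @param n_loc_side Location bins per side.
#' @param n_ang Angular bins (head direction and center bearing).
#' @param n_dist Center-distance bins.
#' @param n_speed Speed bins.
#' @param speed_window Frames in the running-mean speed smoother.
#' @return An object of class `glm_design`: integer matrix `idx` (frames x
#'   variables, 1-based bins), `nbins`, response `n`, `dt`.
#' @export
build_design <- function(tracking, spikes, arena,
                         n_loc_side = 20, n_ang = 30, n_dist = 10,
                         n_speed = 10, speed_window = 5) {
  assert_tracking(tracking)
  L <- arena$side_length
  if (any(tracking$x_cm < 0 | tracking$x_cm > L |
          tracking$y_cm < 0 | tracking$y_cm > L)) {
    abort("tracking contains positions outside the arena")
  }
  dt <- frame_dt(tracking)
  T_ <- nrow(tracking)

  bx <- pmin(floor(tracking$x_cm / (L / n_loc_side)), n_loc_side - 1)
  by <- pmin(floor(tracking$y_cm / (L / n_loc_side)), n_loc_side - 1)
  loc <- by * n_loc_side + bx + 1L

  hd <- pmin(floor(wrap_360(tracking$hd_deg) / (360 / n_ang)), n_ang - 1) + 1L

  bearing <- egocentric_bearing(tracking$x_cm, tracking$y_cm, tracking$hd_deg,
                                arena$center)
  # carry the last defined bearing across the (rare) frames on the center
  if (all(is.na(bearing))) {
    bearing <- rep(0, T_)
  } else if (anyNA(bearing)) {
    bearing <- stats::approx(seq_len(T_)[!is.na(bearing)], bearing[!is.na(bearing)],
                             xout = seq_len(T_), method = "constant",
                             rule = 2, f = 0)$y
  }
  cb <- pmin(floor(wrap_360(bearing) / (360 / n_ang)), n_ang - 1) + 1L

  d <- sqrt((tracking$x_cm - arena$center[1])^2 +
              (tracking$y_cm - arena$center[2])^2)
  dmax <- L / sqrt(2)
  cd <- pmin(floor(d / (dmax / n_dist)), n_dist - 1) + 1L

  step <- sqrt(diff(tracking$x_cm)^2 + diff(tracking$y_cm)^2) / diff(tracking$time_s)
  speed_raw <- c(step[1], step)
  kern <- rep(1 / speed_window, speed_window)
  speed <- as.numeric(stats::filter(speed_raw, kern, sides = 2))
  speed[is.na(speed)] <- speed_raw[is.na(speed)]
  smax <- max(speed) + 1e-9
  sp <- pmin(floor(speed / (smax / n_speed)), n_speed - 1) + 1L

  idx <- cbind(location = as.integer(loc), hd = as.integer(hd),
               center_bearing = as.integer(cb),
               center_distance = as.integer(cd), speed = as.integer(sp))
  n <- tabulate(spikes_to_frames(spikes, tracking$time_s, dt), nbins = T_)
  structure(
    list(
      idx = idx,
      nbins = c(location = n_loc_side^2, hd = n_ang, center_bearing = n_ang,
                center_distance = n_dist, speed = n_speed),
      n_loc_side = n_loc_side, n = n, dt = dt, n_frames = T_,
      n_spikes = sum(n)
    ),
    class = "glm_design"
  )
}

#' Poisson log-likelihood of a spike-count vector given a rate vector
#'
#' \eqn{l = \sum_t [n_t \log r_t - r_t - \log(n_t!)]}, with `r` the expected
#' count per time bin.
#'
#' @param n Non-negative integer counts.
#' @param r Positive expected counts.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(n, r) {
  if (any(r <= 0)) abort("all rates must be positive")
  sum(n * log(r) - r - lgamma(n + 1))
}

# Graph Laplacians encoding the smoothing-penalty adjacency: circular for
# angular variables, a chain for distance/speed, 4-neighbor grid for the
# 2D location bins. Penalty = 0.5 * sum_i S_i * beta_i' L_i beta_i.
penalty_laplacian <- function(var, nbins, n_loc_side) {
  edges <- switch(var,
    location = {
      g <- n_loc_side
      id <- function(ix, iy) (iy - 1) * g + ix
      horiz <- cbind(id(1:(g - 1), rep(1:g, each = g - 1)),
                     id(2:g, rep(1:g, each = g - 1)))
      vert <- cbind(id(rep(1:g, each = g - 1), 1:(g - 1)),
                    id(rep(1:g, each = g - 1), 2:g))
      rbind(horiz, vert)
    },
    hd = , center_bearing = cbind(1:nbins, c(2:nbins, 1)),
    cbind(1:(nbins - 1), 2:nbins)
  )
  L <- matrix(0, nbins, nbins)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    L[a, a] <- L[a, a] + 1; L[b, b] <- L[b, b] + 1
    L[a, b] <- L[a, b] - 1; L[b, a] <- L[b, a] - 1
  }
  L
}

#' Fit the penalized Poisson encoding model
#'
#' Maximizes the penalized log-likelihood `l - P` for the included variables,
#' where `P` penalizes squared differences between adjacent bins of each
#' parameter vector (circularly for angular variables, along the chain for
#' distance and speed, over the 4-neighbor grid for 2D location). The
#' optimizer is L-BFGS-B with the analytic gradient, initialized at zero
#' (or a supplied warm start), run until the projected gradient is below
#' `1e-6` or 500 iterations.
#'
#' @param design A [build_design()] result.
#' @param variables Character subset of
#'   `c("location", "hd", "center_bearing", "center_distance", "speed")`.
#' @param S Named smoothing hyperparameters (defaults: 2 for location, 20
#'   otherwise).
#' @param frames Integer frame indices to fit on (training rows); defaults
#'   to all frames.
#' @param init Optional warm-start parameter vector.
#' @param maxit Iteration cap.
#' @return Object of class `glm_fit`: `beta` (named list of per-variable
#'   parameter vectors), `loglik` (unpenalized, with the `log(n!)` term),
#'   `penalty`, `converged`, `counts` (optimizer iterations).
#' @export
fit_glm <- function(design, variables = glm_variables, S = default_smoothing(),
                    frames = NULL, init = NULL, maxit = 500) {
  stopifnot(inherits(design, "glm_design"))
  variables <- match.arg(variables, glm_variables, several.ok = TRUE)
  frames <- frames %||% seq_len(design$n_frames)
  idx <- design$idx[frames, variables, drop = FALSE]
  n <- design$n[frames]
  nb <- design$nbins[variables]
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  P <- sum(nb)
  Q <- matrix(0, P, P)  # combined penalty matrix (block diagonal)
  for (v in seq_along(variables)) {
    rng <- (offsets[v] + 1):(offsets[v] + nb[v])
    Q[rng, rng] <- S[[variables[v]]] *
      penalty_laplacian(variables[v], nb[v], design$n_loc_side)
  }
  # optim calls fn and gr separately at the same point; cache the last
  # likelihood/gradient evaluation to avoid recomputing it
  cache <- new.env(parent = emptyenv())
  evaluate <- function(beta) {
    if (!is.null(cache$beta) && identical(cache$beta, beta)) return(cache$res)
    res <- glm_nll_grad(beta, idx, n, offsets)
    Qb <- Q %*% beta
    cache$beta <- beta
    cache$res <- list(value = res$nll + 0.5 * sum(beta * Qb),
                      grad = res$grad + as.numeric(Qb))
    cache$res
  }
  fn <- function(beta) evaluate(beta)$value
  gr <- function(beta) evaluate(beta)$grad
  beta0 <- init %||% numeric(P)
  opt <- optim(beta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = 1e-6, factr = 1e4))
  beta <- opt$par
  rate <- exp(glm_eta(beta, idx, offsets))
  fit <- list(
    beta = purrr::map2(seq_along(variables), variables, function(v, nm) {
      beta[(offsets[v] + 1):(offsets[v] + nb[v])]
    }),
    variables = variables, offsets = offsets, nbins = nb,
    par = beta,
    loglik = poisson_loglik(n, pmax(rate, 1e-12)),
    penalty = 0.5 * sum(beta * (Q %*% beta)),
    converged = opt$convergence == 0,
    message = opt$message, counts = opt$counts
  )
  names(fit$beta) <- variables
  structure(fit, class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> vars: %s; loglik %.1f; penalty %.2f; converged: %s\n",
              paste(x$variables, collapse = "+"), x$loglik, x$penalty,
              x$converged))
  invisible(x)
}

# Test log-likelihood of a variable subset, taking the relevant beta blocks
# from a full-model fit and rescaling the subset rate so its time-averaged
# rate on the training frames matches the training mean rate.
subset_test_loglik <- function(fit, design, subset, train_frames, test_frames) {
  if (length(subset) == 0) {
    r0 <- mean(design$n[train_frames])
    return(poisson_loglik(design$n[test_frames], rep(max(r0, 1e-12),
                                                     length(test_frames))))
  }
  beta <- unlist(fit$beta[subset], use.names = FALSE)
  nb <- fit$nbins[subset]
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  eta_train <- glm_eta(beta, design$idx[train_frames, subset, drop = FALSE], offsets)
  eta_test <- glm_eta(beta, design$idx[test_frames, subset, drop = FALSE], offsets)
  scale <- mean(design$n[train_frames]) / mean(exp(eta_train))
  r <- pmax(exp(eta_test) * scale, 1e-12)
  poisson_loglik(design$n[test_frames], r)
}

all_subsets <- function(vars) {
  unlist(lapply(seq_along(vars), function(m) {
    utils::combn(vars, m, simplify = FALSE)
  }), recursive = FALSE)
}

#' Cross-validated forward selection of encoding variables
#'
#' Splits the session into `k` contiguous folds. For each fold the full
#' five-variable model is fit on the training nine-tenths; test
#' log-likelihoods of every variable subset are computed from the relevant
#' blocks of the full-model fit (rate rescaled to the training mean rate).
#' Model size grows forward: the best (m+1)-variable model must beat the
#' best m-variable model by a one-sided Wilcoxon signed-rank test across
#' folds, otherwise the simpler model is kept. The final model must beat a
#' mean-firing-rate-only model, else the cell is `"unclassified"`.
#'
#' @inheritParams fit_glm
#' @param k Number of contiguous folds.
#' @param alpha Significance level for the fold-wise comparisons.
#' @param min_spikes Minimum spike count to attempt classification.
#' @return Object of class `glm_selection`: `selected` (character vector,
#'   empty if unclassified), `classified`, `fold_loglik` (tibble:
#'   fold, subset, loglik), `comparisons` (tibble of Wilcoxon steps),
#'   `full_fit`, `converged`.
#' @export
forward_select <- function(design, k = 10, alpha = 0.05,
                           S = default_smoothing(), min_spikes = 100,
                           maxit = 500) {
  stopifnot(inherits(design, "glm_design"))
  if (k < 2) abort("k must be >= 2")
  vars <- glm_variables
  if (design$n_spikes < min_spikes) {
    return(structure(list(
      selected = character(0), classified = FALSE,
      reason = sprintf("only %d spikes (< %d)", design$n_spikes, min_spikes),
      fold_loglik = tibble::tibble(), comparisons = tibble::tibble(),
      full_fit = NULL, converged = NA
    ), class = "glm_selection"))
  }
  full <- fit_glm(design, vars, S = S, maxit = maxit)
  bounds <- floor(seq(0, design$n_frames, length.out = k + 1))
  subsets <- all_subsets(vars)
  subset_id <- vapply(subsets, paste, collapse = "+", FUN.VALUE = "")

  fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
    test <- (bounds[f] + 1):bounds[f + 1]
    train <- setdiff(seq_len(design$n_frames), test)
    fit_f <- fit_glm(design, vars, S = S, frames = train,
                     init = full$par, maxit = maxit)
    ll <- vapply(subsets, subset_test_loglik, numeric(1),
                 fit = fit_f, design = design,
                 train_frames = train, test_frames = test)
    ll0 <- subset_test_loglik(fit_f, design, character(0), train, test)
    tibble::tibble(
      fold = f,
      subset = c(subset_id, "(mean rate)"),
      size = c(lengths(subsets), 0L),
      loglik = c(ll, ll0),
      converged = fit_f$converged
    )
  })

  mean_ll <- fold_rows |>
    dplyr::group_by(.data$subset, .data$size) |>
    dplyr::summarise(mean_loglik = mean(.data$loglik), .groups = "drop")
  best_by_size <- mean_ll |>
    dplyr::filter(.data$size > 0) |>
    dplyr::group_by(.data$size) |>
    dplyr::slice_max(.data$mean_loglik, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$size)

  get_folds <- function(id) {
    fold_rows$loglik[fold_rows$subset == id][order(fold_rows$fold[fold_rows$subset == id])]
  }
  wilcox_p <- function(bigger, smaller) {
    suppressWarnings(
      stats::wilcox.test(bigger, smaller, paired = TRUE,
                         alternative = "greater")$p.value
    )
  }

  comparisons <- tibble::tibble(step = character(0), p_value = numeric(0))
  current <- best_by_size$subset[1]
  for (m in seq_len(nrow(best_by_size) - 1)) {
    challenger <- best_by_size$subset[m + 1]
    p <- wilcox_p(get_folds(challenger), get_folds(current))
    comparisons <- dplyr::bind_rows(comparisons, tibble::tibble(
      step = paste0(challenger, " vs ", current), p_value = p
    ))
    if (is.na(p) || p >= alpha) break
    current <- challenger
  }
  p_mean <- wilcox_p(get_folds(current), get_folds("(mean rate)"))
  comparisons <- dplyr::bind_rows(comparisons, tibble::tibble(
    step = paste0(current, " vs (mean rate)"), p_value = p_mean
  ))
  classified <- !is.na(p_mean) && p_mean < alpha
  structure(list(
    selected = if (classified) strsplit(current, "+", fixed = TRUE)[[1]] else character(0),
    classified = classified,
    reason = if (classified) NULL else "no model beat the mean-rate model",
    fold_loglik = fold_rows, comparisons = comparisons,
    full_fit = full, converged = all(fold_rows$converged)
  ), class = "glm_selection")
}

#' @export
print.glm_selection <- function(x, ...) {
  sel <- if (length(x$selected) > 0) paste(x$selected, collapse = "+")
         else "unclassified"
  cat(sprintf("<glm_selection> %s\n", sel))
  invisible(x)
}

#' @rdname tidy_openfieldr
#' @export
tidy.glm_selection <- function(x, ...) x$fold_loglik

#' @rdname tidy_openfieldr
#' @export
glance.glm_selection <- function(x, ...) {
  tibble::tibble(
    selected = paste(x$selected, collapse = "+"),
    classified = x$classified,
    n_comparisons = nrow(x$comparisons),
    p_vs_mean_rate = if (nrow(x$comparisons) > 0) {
      x$comparisons$p_value[nrow(x$comparisons)]
    } else NA_real_,
    converged = x$converged
  )
}
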