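#' Default analysis configuration
#'
#' Every numeric default of the pipeline in one list: spatial and angular
#' bin sizes, smoothing width, shuffle settings, GLM smoothing
#' hyperparameters and fold count, and the fixed classification criteria.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    bin_size = 2.5, smooth_sigma = 3.75,
    ang_bin_width = 12, dist_bin_width = 4,
    n_shuffles = 400, shuffle_percentile = 99, min_shift = 30,
    S = as.list(default_smoothing()), k = 10, alpha = 0.05, min_spikes = 100,
    grid_cut = 0.4, border_cut = 0.5, mvl_floor = 0.2, peak_floor = 1,
    resample_bin = 15, mvl_grid = 20
  )
}

#' Write a session to disk in the pipeline's plain-text formats
#'
#' Tracking goes to `tracking.csv` (header `time_s,x_cm,y_cm,hd_deg`), each
#' cell's spikes to `<cell_id>.txt` (one timestamp per line), and a YAML
#' manifest records arena geometry, cue configuration, session role and the
#' ground-truth model parameters of synthetic cells.
#'
#' @param session A `session` object (see [simulate_session()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$tracking[, c("time_s", "x_cm", "y_cm", "hd_deg")],
                   file.path(dir, "tracking.csv"), row.names = FALSE)
  for (id in names(session$spikes)) {
    writeLines(format(session$spikes[[id]], digits = 10, trim = TRUE,
                      scientific = FALSE),
               file.path(dir, paste0(id, ".txt")))
  }
  serialize_model <- function(m) {
    if (is.null(m)) return(NULL)
    out <- unclass(m)
    if (!is.null(out$fields)) out$fields <- as.list(out$fields)
    out
  }
  manifest <- list(
    session = list(id = session$id, role = session$role,
                   cue_wall = session$cue_wall),
    arena = list(side_length = session$arena$side_length,
                 goal_center = session$arena$goal_center,
                 goal_side = session$arena$goal_side,
                 cue_wall = session$arena$cue_wall),
    tracking_file = "tracking.csv",
    cells = purrr::map(names(session$spikes), function(id) {
      list(cell_id = id, spike_file = paste0(id, ".txt"),
           region = session$cells$region[session$cells$cell_id == id],
           kind = session$cells$kind[session$cells$cell_id == id],
           ground_truth = serialize_model(session$models[[id]]))
    })
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read and validate a session from a manifest
#'
#' Loads the tracking CSV and per-cell spike files referenced by a session
#' manifest. Out-of-arena tracking samples are clipped to the wall with a
#' warning; spikes outside the tracked time span are dropped with the count
#' reported.
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [write_session()].
#' @return A `session` object.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) abort(paste("no manifest at", manifest_path))
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  arena <- arena_geometry(
    side_length = man$arena$side_length,
    goal_center = unlist(man$arena$goal_center),
    goal_side = man$arena$goal_side,
    cue_wall = man$arena$cue_wall
  )
  tpath <- file.path(dir, man$tracking_file)
  tracking <- tibble::as_tibble(utils::read.csv(tpath))
  need <- c("time_s", "x_cm", "y_cm", "hd_deg")
  miss <- setdiff(need, names(tracking))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", tpath, paste(miss, collapse = ", ")))
  }
  if (nrow(tracking) == 0) abort(paste(tpath, "is empty"))
  bad <- which(diff(tracking$time_s) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: time_s not strictly increasing at row %d", tpath, bad[1] + 1))
  }
  n_clip <- sum(tracking$x_cm < 0 | tracking$x_cm > arena$side_length |
                  tracking$y_cm < 0 | tracking$y_cm > arena$side_length)
  if (n_clip > 0) {
    warn(sprintf("%s: clipped %d out-of-arena sample(s) to the walls", tpath, n_clip))
    tracking$x_cm <- pmin(pmax(tracking$x_cm, 0), arena$side_length)
    tracking$y_cm <- pmin(pmax(tracking$y_cm, 0), arena$side_length)
  }
  tracking$hd_deg <- wrap_360(tracking$hd_deg)
  dt <- frame_dt(tracking)
  span_end <- tracking$time_s[nrow(tracking)] + dt

  cells <- man$cells
  spikes <- list()
  meta <- purrr::map_dfr(cells, function(cl) {
    spath <- file.path(dir, cl$spike_file)
    if (!file.exists(spath)) abort(paste("missing spike file", spath))
    raw <- scan(spath, what = numeric(), quiet = TRUE)
    sp <- sort(raw)
    n_drop <- sum(sp < tracking$time_s[1] | sp >= span_end)
    if (n_drop > 0) {
      warn(sprintf("%s: dropped %d spike(s) outside the tracked span",
                   spath, n_drop))
      sp <- sp[sp >= tracking$time_s[1] & sp < span_end]
    }
    spikes[[cl$cell_id]] <<- sp
    tibble::tibble(cell_id = cl$cell_id, kind = cl$kind %||% NA_character_,
                   region = cl$region %||% NA_character_, n_spikes = length(sp))
  })
  structure(
    list(
      id = man$session$id, role = man$session$role %||% "standard1",
      arena = arena, config = NULL, cue_wall = man$session$cue_wall,
      tracking = tracking, spikes = spikes, models = NULL, cells = meta
    ),
    class = "session"
  )
}

# Analyze a single cell of a session: GLM selection, maps, scores, shuffle
# thresholds (computed only for the GLM-selected variables), classification.
analyze_cell <- function(session, cell_id, config = default_config(),
                         seed = 1L, mvl_map_wanted = TRUE) {
  tracking <- session$tracking
  arena <- session$arena
  spikes <- session$spikes[[cell_id]]
  region <- session$cells$region[session$cells$cell_id == cell_id]
  duration <- nrow(tracking) * frame_dt(tracking)

  design <- build_design(tracking, spikes, arena)
  sel <- forward_select(design, k = config$k, alpha = config$alpha,
                        S = unlist(config$S), min_spikes = config$min_spikes)

  map <- compute_rate_map(tracking, spikes, arena, config$bin_size,
                          config$smooth_sigma)
  gs <- grid_score(map)
  bs <- border_score(map)
  si <- spatial_information(map)
  hd_curve <- circular_tuning_curve(tracking, spikes,
                                    bin_width = config$ang_bin_width)
  bearing <- egocentric_bearing(tracking$x_cm, tracking$y_cm, tracking$hd_deg,
                                arena$center)
  cb_curve <- circular_tuning_curve(tracking, spikes, angles = bearing,
                                    bin_width = config$ang_bin_width,
                                    variable = "center_bearing")
  cd_curve <- distance_tuning_curve(tracking, spikes, arena,
                                    config$dist_bin_width)

  seeds <- derive_seeds(seed, 4L)
  thr <- list()
  if ("location" %in% sel$selected) {
    thr$spatial_info <- shuffle_threshold_si(
      tracking, spikes, arena, config$bin_size, config$smooth_sigma,
      n_shuffles = config$n_shuffles, percentile = config$shuffle_percentile,
      min_shift = config$min_shift, seed = seeds[1]
    )
  }
  if ("hd" %in% sel$selected) {
    thr$hd_mvl <- shuffle_threshold_curve_mvl(
      tracking, spikes, bin_width = config$ang_bin_width,
      n_shuffles = config$n_shuffles, percentile = config$shuffle_percentile,
      min_shift = config$min_shift, seed = seeds[2]
    )
  }
  if ("center_bearing" %in% sel$selected) {
    thr$cb_mvl <- shuffle_threshold_curve_mvl(
      tracking, spikes, angles = bearing, bin_width = config$ang_bin_width,
      n_shuffles = config$n_shuffles, percentile = config$shuffle_percentile,
      min_shift = config$min_shift, seed = seeds[3]
    )
  }
  if ("center_distance" %in% sel$selected) {
    # linear and Gaussian R^2 each get their own null distribution, computed
    # on a shared set of circular shifts
    shifts <- with_seed(seeds[4],
                        runif(config$n_shuffles, config$min_shift,
                              duration - config$min_shift))
    null_r2 <- vapply(shifts, function(s) {
      cv <- distance_tuning_curve(
        tracking, shuffle_spike_train(spikes, duration, shift = s),
        arena, config$dist_bin_width
      )
      c(attr(cv, "linear_r2"), attr(cv, "gaussian_r2") %||% NA_real_)
    }, numeric(2))
    thr$cd_linear_r2 <- unname(quantile(null_r2[1, ],
                                        config$shuffle_percentile / 100,
                                        na.rm = TRUE))
    thr$cd_gaussian_r2 <- unname(quantile(null_r2[2, ],
                                          config$shuffle_percentile / 100,
                                          na.rm = TRUE))
  }

  scores <- list(
    grid_score = gs$score, border_score = bs$score, spatial_info = si,
    hd_mvl = mvl(hd_curve), hd_peak = attr(hd_curve, "peak_rate"),
    cb_mvl = mvl(cb_curve), cb_peak = attr(cb_curve, "peak_rate"),
    cd_linear_r2 = attr(cd_curve, "linear_r2"),
    cd_gaussian_r2 = attr(cd_curve, "gaussian_r2"),
    cd_peak = attr(cd_curve, "peak_rate")
  )
  cls <- classify_cell(sel, scores, thr, region = region,
                       grid_cut = config$grid_cut, border_cut = config$border_cut,
                       mvl_floor = config$mvl_floor, peak_floor = config$peak_floor)

  mm <- if (mvl_map_wanted && length(spikes) >= config$min_spikes) {
    tryCatch(mvl_map(tracking, spikes, arena, n_grid = config$mvl_grid,
                     bin_width = config$ang_bin_width),
             error = function(e) NULL)
  } else NULL

  list(
    cell_id = cell_id, region = region, selection = sel, rate_map = map,
    scores = scores, thresholds = thr, classification = cls,
    hd_curve = hd_curve, cb_curve = cb_curve, cd_curve = cd_curve,
    fields = detect_fields(map), mvl_map = mm
  )
}

#' Run the full standard-session analysis for every cell
#'
#' For each cell: penalized-GLM forward selection, rate map and spatial
#' scores, HD/CB/CD tuning curves, shuffle thresholds (seeded; computed
#' only for the GLM-selected variables), egocentric MVL map, firing fields,
#' and the combined classification. Per-cell failures are isolated: a
#' failing cell is reported in the table with its error message rather than
#' aborting the session.
#'
#' @param session A `session` object.
#' @param config Configuration list (see [default_config()]).
#' @param seed Integer seed driving all shuffle randomness.
#' @param mvl_maps Compute per-cell egocentric MVL maps (the slowest step).
#' @return Object of class `session_analysis`: `cells` (per-cell tibble of
#'   scores, thresholds and classification), `details` (named list of
#'   per-cell result objects), `behavior` (zone table), `seed`, `config`.
#' @export
run_standard_analysis <- function(session, config = default_config(),
                                  seed = 1L, mvl_maps = TRUE) {
  stopifnot(inherits(session, "session"))
  ids <- session$cells$cell_id
  seeds <- derive_seeds(seed, length(ids))
  details <- list()
  rows <- purrr::map_dfr(seq_along(ids), function(k) {
    id <- ids[k]
    res <- tryCatch(
      analyze_cell(session, id, config, seed = seeds[k],
                   mvl_map_wanted = mvl_maps),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(cell_id = id, error = conditionMessage(res)))
    }
    details[[id]] <<- res
    s <- res$scores
    tibble::tibble(
      cell_id = id, region = res$region,
      n_spikes = length(session$spikes[[id]]),
      selected = paste(res$selection$selected, collapse = "+"),
      grid_score = s$grid_score, border_score = s$border_score,
      spatial_info = s$spatial_info,
      hd_mvl = s$hd_mvl, hd_peak = s$hd_peak,
      cb_mvl = s$cb_mvl, cb_peak = s$cb_peak,
      cd_linear_r2 = s$cd_linear_r2, cd_gaussian_r2 = s$cd_gaussian_r2,
      cd_peak = s$cd_peak,
      thr_spatial_info = res$thresholds$spatial_info %||% NA_real_,
      thr_hd_mvl = res$thresholds$hd_mvl %||% NA_real_,
      thr_cb_mvl = res$thresholds$cb_mvl %||% NA_real_,
      thr_cd_linear_r2 = res$thresholds$cd_linear_r2 %||% NA_real_,
      thr_cd_gaussian_r2 = res$thresholds$cd_gaussian_r2 %||% NA_real_,
      mvl_max_x = if (is.null(res$mvl_map)) NA_real_ else res$mvl_map$mvl_max_loc[1],
      mvl_max_y = if (is.null(res$mvl_map)) NA_real_ else res$mvl_map$mvl_max_loc[2],
      res$classification[setdiff(names(res$classification), "region")],
      error = NA_character_
    )
  })
  structure(
    list(cells = rows, details = details,
         behavior = behavior_table(session$tracking, session$arena),
         seed = seed, config = config, session_id = session$id),
    class = "session_analysis"
  )
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("<session_analysis> %s: %d cells (seed %s)\n",
              x$session_id, nrow(x$cells), format(x$seed)))
  if ("label" %in% names(x$cells)) {
    print(table(x$cells$label))
  }
  invisible(x)
}

#' Population summaries on raw and occupancy-resampled data
#'
#' Computes the population egocentric MVL summary (MVL_max histogram, mean
#' normalized MVL map, goal-zone versus equivalent-zone mean MVL) and the
#' population normalized rate map for a set of cells, on the raw session
#' and, optionally, on an occupancy-equalized resample of it. Each summary
#' carries a `resampled` flag in its metadata.
#'
#' @param session A `session` object.
#' @param cell_ids Cells to include (default: all).
#' @param config Configuration list (see [default_config()]).
#' @param resample Also compute the occupancy-resampled variants.
#' @param seed Seed for the resampling draw.
#' @return List of summaries; each element has `resampled`, `mvl` (from
#'   [population_mvl_summary()]) and `rate` (from
#'   [population_normalized_map()]).
#' @export
run_population_summaries <- function(session, cell_ids = NULL,
                                     config = default_config(),
                                     resample = TRUE, seed = 1L) {
  stopifnot(inherits(session, "session"))
  cell_ids <- cell_ids %||% session$cells$cell_id
  build <- function(tracking, spikes_list, resampled) {
    maps <- purrr::map(spikes_list, function(sp) {
      compute_rate_map(tracking, sp, session$arena, config$bin_size,
                       config$smooth_sigma)
    })
    mvls <- purrr::map(spikes_list, function(sp) {
      mvl_map(tracking, sp, session$arena, n_grid = config$mvl_grid,
              bin_width = config$ang_bin_width)
    })
    list(
      resampled = resampled,
      mvl = population_mvl_summary(mvls, session$arena),
      rate = population_normalized_map(maps, session$arena)
    )
  }
  out <- list(raw = build(session$tracking, session$spikes[cell_ids], FALSE))
  if (resample) {
    seeds <- derive_seeds(seed, length(cell_ids))
    rs <- purrr::map2(session$spikes[cell_ids], seq_along(cell_ids),
                      function(sp, k) {
                        resample_equal_occupancy(session$tracking, sp,
                                                 session$arena,
                                                 config$resample_bin,
                                                 seed = seeds[k])
                      })
    # each cell shares the session trajectory, so one resampled tracking
    # (first cell's draw) is paired with its own spike subset per cell
    out$resampled <- list(
      resampled = TRUE,
      mvl = population_mvl_summary(
        purrr::map(rs, function(r) {
          mvl_map(r$tracking, r$spikes, session$arena,
                  n_grid = config$mvl_grid, bin_width = config$ang_bin_width)
        }),
        session$arena
      ),
      rate = population_normalized_map(
        purrr::map(rs, function(r) {
          compute_rate_map(r$tracking, r$spikes, session$arena,
                           config$bin_size, config$smooth_sigma)
        }),
        session$arena
      )
    )
  }
  out
}

#' Cue-manipulation analysis of a standard/manipulation/standard triplet
#'
#' Per cell (present in all three sessions): HD tuning curves and preferred
#' direction per session, the preferred-direction shift from standard 1 to
#' the manipulation session, bidirectionality index per session and its
#' change, and rotated-map correlations between standard 1 and the
#' manipulation session. For the duplication scenario a bidirectional von
#' Mises fit of the manipulation-session curve yields the south/north cue
#' modulation indices (trough mode for POR cells whose standard-session
#' preferred direction points away from the south cue). Optionally,
#' egocentric MVL_max rotation about the arena center is computed for named
#' cells. Population-level Rayleigh and V tests summarize the shift
#' distribution.
#'
#' @param triplet A `session_triplet`.
#' @param config Configuration list.
#' @param mvl_cells Cell ids for which MVL_max rotation is computed
#'   (`NULL` for none, `"auto"` for cells of generative kind `cb_x_hd`).
#' @param expected_shift_deg Predicted shift for the V test; defaults to
#'   the scenario's cue rotation.
#' @return Object of class `cue_analysis`: `cells` tibble and `population`
#'   tibble (Rayleigh/V tests on the shift distribution).
#' @export
run_cue_analysis <- function(triplet, config = default_config(),
                             mvl_cells = NULL, expected_shift_deg = NULL) {
  stopifnot(inherits(triplet, "session_triplet"))
  s1 <- triplet$sessions[[1]]
  s2 <- triplet$sessions[[2]]
  s3 <- triplet$sessions[[3]]
  ids <- Reduce(intersect, list(names(s1$spikes), names(s2$spikes),
                                names(s3$spikes)))
  if (identical(mvl_cells, "auto")) {
    mvl_cells <- s1$cells$cell_id[s1$cells$kind == "cb_x_hd"]
  }
  expected <- expected_shift_deg %||% scenario_rotation(triplet$scenario)

  rows <- purrr::map_dfr(ids, function(id) {
    region <- s1$cells$region[s1$cells$cell_id == id]
    curves <- purrr::map(list(s1, s2, s3), function(s) {
      circular_tuning_curve(s$tracking, s$spikes[[id]],
                            bin_width = config$ang_bin_width)
    })
    shift <- preferred_direction_shift(curves[[1]], curves[[2]])
    bis <- purrr::map_dbl(list(s1, s2, s3), function(s) {
      bidirectionality_index(s$tracking, s$spikes[[id]],
                             bin_width = config$ang_bin_width)$bi
    })
    mi_s <- mi_n <- NA_real_
    if (triplet$scenario == "duplication") {
      pref1 <- preferred_direction(curves[[1]])
      # the south cue sits at bearing -90 deg from the arena center; POR
      # cells firing away from it are fitted in trough mode
      away <- !is.na(pref1) && abs(circ_diff(pref1, 270)) > 90
      mode <- if (region == "POR" && away) "trough" else "peak"
      fit <- tryCatch(fit_bidirectional_von_mises(curves[[2]], mode = mode),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        anchor <- if (mode == "trough") wrap_360(pref1 + 180) else pref1
        mi <- cue_modulation_indices(fit, anchor)
        mi_s <- mi$mi_south; mi_n <- mi$mi_north
      }
    }
    maps <- purrr::map(list(s1, s2), function(s) {
      compute_rate_map(s$tracking, s$spikes[[id]], s$arena,
                       config$bin_size, config$smooth_sigma)
    })
    rmc <- rotated_map_correlations(maps[[1]], maps[[2]])
    rot <- NA_real_
    if (id %in% (mvl_cells %||% character(0))) {
      mm <- purrr::map(list(s1, s2), function(s) {
        mvl_map(s$tracking, s$spikes[[id]], s$arena,
                n_grid = config$mvl_grid, bin_width = config$ang_bin_width)
      })
      rot <- mvlmax_rotation_about_center(mm[[1]]$mvl_max_loc,
                                          mm[[2]]$mvl_max_loc,
                                          s1$arena$center)
    }
    tibble::tibble(
      cell_id = id, region = region,
      kind = s1$cells$kind[s1$cells$cell_id == id],
      pref_s1 = preferred_direction(curves[[1]]),
      pref_s2 = preferred_direction(curves[[2]]),
      pref_s3 = preferred_direction(curves[[3]]),
      shift_deg = shift,
      bi_s1 = bis[1], bi_s2 = bis[2], bi_s3 = bis[3],
      delta_bi = bis[2] - bis[1],
      mi_south = mi_s, mi_north = mi_n,
      mvlmax_rotation_deg = rot,
      map_corr_0 = rmc$correlation[1], map_corr_90 = rmc$correlation[2],
      map_corr_180 = rmc$correlation[3], map_corr_270 = rmc$correlation[4]
    )
  })

  population <- if (nrow(rows) >= 2 && sum(!is.na(rows$shift_deg)) >= 2) {
    shifts <- rows$shift_deg[!is.na(rows$shift_deg)]
    ray <- rayleigh_test(shifts)
    vt <- v_test(shifts, expected)
    tibble::tibble(
      test = c("rayleigh", "v_test"),
      statistic = c(ray$r, vt$u),
      p_value = c(ray$p_value, vt$p_value),
      mean_shift_deg = rep(ray$mean_deg, 2),
      expected_deg = c(NA_real_, expected),
      n = c(ray$n, vt$n)
    )
  } else {
    if (nrow(rows) == 0) warn("empty cell roster: no cue analysis computed")
    tibble::tibble()
  }
  structure(list(cells = rows, population = population,
                 scenario = triplet$scenario),
            class = "cue_analysis")
}

#' @export
print.cue_analysis <- function(x, ...) {
  cat(sprintf("<cue_analysis> %s: %d cells\n", x$scenario, nrow(x$cells)))
  if (nrow(x$population) > 0) print(x$population)
  invisible(x)
}
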