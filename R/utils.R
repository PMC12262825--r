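#' @importFrom rlang abort warn %||% .data
#' @importFrom stats quantile median sd coef lm optim rpois runif rnorm fft
#'   pnorm wilcox.test complete.cases
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into a standard interval
#'
#' `wrap_360()` maps angles (degrees) into `[0, 360)`; `wrap_180()` maps
#' signed angular differences into `[-180, 180)`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of wrapped angles.
#' @export
wrap_360 <- function(x) x %% 360

#' @rdname wrap_360
#' @export
wrap_180 <- function(x) ((x + 180) %% 360) - 180

#' Signed circular difference a - b in degrees, wrapped to [-180, 180)
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
circ_diff <- function(a, b) wrap_180(a - b)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# All exported stochastic functions take an explicit `seed` argument and pass
# through here, so there is no hidden global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Nominal frame interval of a tracking table (s). Resampled (gapped)
# tracking carries the original interval in attribute "dt".
frame_dt <- function(tracking) {
  attr(tracking, "dt") %||% stats::median(diff(tracking$time_s))
}

# Assign spike times to tracking frames: frame f covers [t_f, t_f + dt).
# Returns integer frame indices, NA for spikes outside any frame window
# (tracking may be gapped after occupancy resampling).
spikes_to_frames <- function(spike_times, time_s, dt = NULL) {
  if (length(spike_times) == 0) return(integer(0))
  dt <- dt %||% stats::median(diff(time_s))
  idx <- findInterval(spike_times, time_s)
  idx[idx == 0L] <- NA_integer_
  ok <- !is.na(idx)
  idx[ok][spike_times[ok] >= time_s[idx[ok]] + dt] <- NA_integer_
  idx
}

assert_tracking <- function(tracking) {
  need <- c("time_s", "x_cm", "y_cm", "hd_deg")
  miss <- setdiff(need, names(tracking))
  if (length(miss) > 0) {
    abort(paste0("tracking is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(tracking) == 0) abort("tracking is empty")
  if (any(diff(tracking$time_s) <= 0)) abort("tracking time_s must be strictly increasing")
  invisible(tracking)
}
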