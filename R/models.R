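#' Ground-truth tuning models for synthetic cells
#'
#' Constructs a generative firing-rate model of one of the canonical
#' open-field cell types. The model maps the animal's instantaneous state
#' (position, head direction) to a firing rate in Hz, which the spike
#' generator turns into an inhomogeneous Poisson spike train.
#'
#' Supported kinds:
#' \describe{
#'   \item{grid}{Three-cosine hexagonal lattice with `spacing` (cm),
#'     `orientation_deg`, spatial `phase` (cm, cm) and a `sharpness` exponent
#'     that narrows the fields.}
#'   \item{border}{Exponential rate decay with distance from `preferred_wall`
#'     (decay constant `decay_cm`).}
#'   \item{nongrid}{Sum of isotropic Gaussian fields (`fields`: data frame
#'     with columns `x`, `y`, `width`, `amplitude`).}
#'   \item{hd}{Von Mises tuning to allocentric head direction
#'     (`preferred_deg`, concentration `kappa`).}
#'   \item{lm_hd}{Landmark-modulated HD cell: as `hd`, but its preferred
#'     direction follows cue rotations with gain `cue_gain` and splits into
#'     two lobes 180 degrees apart (mixture weight `duplication_weight` on
#'     the opposite lobe) under cue duplication.}
#'   \item{cb}{Von Mises tuning to the egocentric bearing of a reference
#'     point (`reference`, default the arena center) at `preferred_deg`.}
#'   \item{cd}{Tuning to distance from the arena center; `profile` is
#'     `"linear"` (signed `slope_sign`) or `"gaussian"` (`mu_cm`, `width_cm`).}
#'   \item{cb_x_hd}{Conjunctive product of a `cb` component (with an offset
#'     reference point) and an `hd` component.}
#' }
#'
#' @param kind Cell type; one of `"grid"`, `"border"`, `"nongrid"`, `"hd"`,
#'   `"cb"`, `"cd"`, `"cb_x_hd"`, `"lm_hd"`.
#' @param baseline_rate Baseline firing rate (Hz).
#' @param peak_rate Peak firing rate (Hz); must be `>= baseline_rate`.
#' @param region Brain-region tag, `"POR"` or `"MEC_PaS"`; POR-like cells
#'   respond to visual-cue manipulations, MEC-like cells do not. Defaults by
#'   kind.
#' @param ... Kind-specific parameters (see Details).
#' @return An object of class `tuning_model`.
#' @export
tuning_model <- function(kind = c("grid", "border", "nongrid", "hd", "cb",
                                  "cd", "cb_x_hd", "lm_hd"),
                         baseline_rate = 0.5, peak_rate = 10,
                         region = NULL, ...) {
  kind <- match.arg(kind)
  if (baseline_rate < 0 || peak_rate < baseline_rate) {
    abort("need 0 <= baseline_rate <= peak_rate")
  }
  extra <- list(...)
  defaults <- switch(kind,
    grid = list(spacing = 40, orientation_deg = 0, phase = c(0, 0), sharpness = 2),
    border = list(preferred_wall = "south", decay_cm = 8),
    nongrid = list(fields = data.frame(x = c(40, 85), y = c(80, 30),
                                       width = c(12, 9), amplitude = c(1, 0.8))),
    hd = list(preferred_deg = 0, kappa = 4),
    lm_hd = list(preferred_deg = 0, kappa = 4, cue_gain = 1,
                 duplication_weight = 0.5, lobe_weight = 0),
    cb = list(preferred_deg = 0, kappa = 4, reference = NULL),
    cd = list(profile = "linear", slope_sign = 1, mu_cm = 30, width_cm = 12),
    # conjunctive cells are bearing-dominant: with HD concentration rivaling
    # the bearing concentration, the reference point is not identifiable from
    # the MVL map (HD tuning leaks into bearing tuning at distant reference
    # points and pushes the argmax outward even in the noiseless limit)
    cb_x_hd = list(preferred_deg = 0, kappa = 4, reference = c(90, 90),
                   hd_preferred_deg = 0, hd_kappa = 1)
  )
  params <- utils::modifyList(defaults, extra)
  if (!is.null(params$kappa) && params$kappa < 0) abort("kappa must be >= 0")
  for (f in c("cue_gain", "duplication_weight", "lobe_weight")) {
    if (!is.null(params[[f]]) && (params[[f]] < 0 || params[[f]] > 1)) {
      abort(paste(f, "must lie in [0, 1]"))
    }
  }
  region <- region %||% switch(kind,
    grid = , border = , nongrid = , hd = "MEC_PaS",
    cb = , cd = , cb_x_hd = , lm_hd = "POR"
  )
  structure(
    c(list(kind = kind, baseline_rate = baseline_rate, peak_rate = peak_rate,
           region = region), params),
    class = "tuning_model"
  )
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("<tuning_model> %s (%s), %g-%g Hz\n",
              x$kind, x$region, x$baseline_rate, x$peak_rate))
  invisible(x)
}

vm_profile <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - mu_deg)) - 1))
}

# Normalized (max 1) tuning profile of the model over frames.
model_profile <- function(model, x, y, hd, arena) {
  ctr <- arena$center
  switch(model$kind,
    grid = {
      kmag <- 4 * pi / (sqrt(3) * model$spacing)
      angs <- deg2rad(model$orientation_deg + c(0, 60, 120))
      px <- x - model$phase[1]
      py <- y - model$phase[2]
      s <- rowSums(sapply(angs, function(a) cos(kmag * (cos(a) * px + sin(a) * py))))
      ((s + 1.5) / 4.5)^model$sharpness
    },
    border = {
      d <- switch(model$preferred_wall,
        south = y, north = arena$side_length - y,
        west = x, east = arena$side_length - x
      )
      exp(-d / model$decay_cm)
    },
    nongrid = {
      f <- model$fields
      g <- rep(0, length(x))
      for (i in seq_len(nrow(f))) {
        g <- g + f$amplitude[i] *
          exp(-((x - f$x[i])^2 + (y - f$y[i])^2) / (2 * f$width[i]^2))
      }
      pmin(g / max(f$amplitude), 1)
    },
    hd = vm_profile(hd, model$preferred_deg, model$kappa),
    lm_hd = {
      w <- model$lobe_weight
      (1 - w) * vm_profile(hd, model$preferred_deg, model$kappa) +
        w * vm_profile(hd, model$preferred_deg + 180, model$kappa)
    },
    cb = {
      ref <- model$reference %||% ctr
      b <- egocentric_bearing(x, y, hd, ref)
      p <- vm_profile(b, model$preferred_deg, model$kappa)
      p[is.na(b)] <- 0   # on top of the reference point: bearing undefined
      p
    },
    cd = {
      d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
      dmax <- arena$side_length / sqrt(2)
      if (model$profile == "linear") {
        if (model$slope_sign >= 0) d / dmax else 1 - d / dmax
      } else {
        exp(-(d - model$mu_cm)^2 / (2 * model$width_cm^2))
      }
    },
    cb_x_hd = {
      b <- egocentric_bearing(x, y, hd, model$reference)
      p <- vm_profile(b, model$preferred_deg, model$kappa) *
        vm_profile(hd, model$hd_preferred_deg, model$hd_kappa)
      p[is.na(b)] <- 0
      p
    },
    abort(paste("unknown model kind:", model$kind))
  )
}

#' Instantaneous firing rate of a tuning model along a trajectory
#'
#' @param model A [tuning_model()].
#' @param tracking Tracking tibble (`time_s`, `x_cm`, `y_cm`, `hd_deg`).
#' @param arena An [arena_geometry()].
#' @return Numeric vector of rates (Hz), one per frame; always `>= 0`.
#' @export
model_rate <- function(model, tracking, arena) {
  assert_tracking(tracking)
  g <- model_profile(model, tracking$x_cm, tracking$y_cm, tracking$hd_deg, arena)
  r <- model$baseline_rate + (model$peak_rate - model$baseline_rate) * g
  if (any(r < 0)) abort("tuning model produced a negative rate")
  r
}
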