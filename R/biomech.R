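#' Arterial pressure specification
#'
#' Converts a standardized cuff pressure (default 140/80 mm Hg, the
#' value used for all computations) into the analysis pressure in kPa:
#' either the mean arterial pressure, `diastolic + (systolic -
#' diastolic)/3`, or the systolic pressure, times 0.133322 kPa/mm Hg.
#'
#' @param systolic,diastolic mm Hg; `systolic > diastolic > 0`.
#' @param analysis `"map"` (mean arterial pressure, default) or
#'   `"systolic"`.
#' @return list of class `pressure_spec` with `systolic_mmHg`,
#'   `diastolic_mmHg`, `analysis`, `analysis_pressure_kpa`.
#' @export
pressure_spec <- function(systolic = 140, diastolic = 80,
                          analysis = c("map", "systolic")) {
  analysis <- match.arg(analysis)
  if (!(systolic > diastolic && diastolic > 0)) {
    stop("need systolic > diastolic > 0 mm Hg", call. = FALSE)
  }
  mmhg <- if (analysis == "map") diastolic + (systolic - diastolic) / 3 else
    systolic
  structure(list(systolic_mmHg = systolic, diastolic_mmHg = diastolic,
                 analysis = analysis,
                 analysis_pressure_kpa = mmhg * 0.133322),
            class = "pressure_spec")
}

#' Analytic wall-stress and rupture-index surrogate
#'
#' A deliberately simple, fully documented analytic stand-in for
#' patient-specific finite-element wall-stress computation. Per
#' centerline station `s`, wall stress follows a thin-wall (Laplace)
#' estimate with exponential stress buffering by the intraluminal
#' thrombus:
#'
#' `stress(s) = P * r_outer(s) / (2 * wall_thickness) *
#'   exp(-ilt_attenuation * ilt_thickness(s))`
#'
#' The spherical form `P*r/(2t)` is used (rather than cylindrical
#' `P*r/t`) because a fusiform sac is closer to a spherical cap at the
#' bulge; the choice affects only the overall scale. Wall strength
#' decreases linearly with ILT thickness down to a floor:
#'
#' `strength(s) = max(floor, base_strength -
#'   ilt_strength_loss * ilt_thickness(s))`
#'
#' The rupture index is `stress/strength` per station. The surrogate's
#' role is to produce plausible, controllable stress/strength maxima for
#' the motion pipeline; it does not claim quantitative agreement with
#' nonlinear FEM.
#'
#' @param m a [vessel_model()].
#' @param pressure a [pressure_spec()].
#' @param wall_thickness wall thickness, mm (> 0).
#' @param ilt_attenuation ILT stress-attenuation coefficient, 1/mm
#'   (>= 0).
#' @param base_strength nominal wall strength, kPa.
#' @param ilt_strength_loss strength lost per mm of ILT, kPa/mm.
#' @param floor minimum wall strength, kPa (`base_strength > floor >
#'   0`).
#' @return list of class `stress_field`: per-station `stress_kpa`,
#'   `strength_kpa`, `rupture_index`.
#' @export
stress_field <- function(m, pressure = pressure_spec(),
                         wall_thickness = 2, ilt_attenuation = 0.03,
                         base_strength = 800, ilt_strength_loss = 15,
                         floor = 300) {
  stopifnot(inherits(m, "vessel_model"), inherits(pressure, "pressure_spec"),
            wall_thickness > 0, ilt_attenuation >= 0)
  ilt <- m$outer_radius - m$lumen_radius
  stress <- pressure$analysis_pressure_kpa * m$outer_radius /
    (2 * wall_thickness) * exp(-ilt_attenuation * ilt)
  strength <- strength_field(m, base_strength, ilt_strength_loss, floor)
  structure(list(stress_kpa = stress, strength_kpa = strength,
                 rupture_index = stress / strength,
                 pressure = pressure),
            class = "stress_field")
}

#' Per-station wall strength surrogate
#'
#' @inheritParams stress_field
#' @return numeric vector of strengths, kPa.
#' @export
strength_field <- function(m, base_strength = 800, ilt_strength_loss = 15,
                           floor = 300) {
  stopifnot(inherits(m, "vessel_model"))
  if (!(base_strength > floor && floor > 0)) {
    stop("need base_strength > floor > 0 kPa", call. = FALSE)
  }
  ilt <- m$outer_radius - m$lumen_radius
  pmax(floor, base_strength - ilt_strength_loss * ilt)
}

#' Peak wall stress and peak wall rupture index with locations
#'
#' PWS is the maximum stress over stations, PWRI the maximum
#' stress/strength ratio; each is returned with its station index and
#' the station's 3-D centerline point (exported as the `max_pws` /
#' `max_pwri` landmarks). Ties are broken toward the proximal station
#' with a message. The mean-ILT-stress proxy averages stress over
#' stations with positive ILT thickness (`NA` when there is none).
#'
#' @param field a [stress_field()].
#' @param m the [vessel_model()] the field was computed from.
#' @return list of class `biomech_metrics`: `pws_kpa`, `pws_station`,
#'   `pws_position`, `pwri`, `pwri_station`, `pwri_position`,
#'   `mean_ilt_stress_kpa`.
#' @export
biomech_metrics <- function(field, m) {
  stopifnot(inherits(field, "stress_field"), inherits(m, "vessel_model"))
  n <- nrow(m$centerline$points)
  if (length(field$stress_kpa) != n) {
    stop("stress field length differs from centerline length", call. = FALSE)
  }
  pick <- function(v, what) {
    idx <- which(v == max(v))
    if (length(idx) > 1L) {
      message("biomech_metrics: tied ", what,
              " maxima; proximal station ", idx[1L], " reported")
    }
    idx[1L]
  }
  i_pws <- pick(field$stress_kpa, "stress")
  i_pwri <- pick(field$rupture_index, "rupture-index")
  ilt <- m$outer_radius - m$lumen_radius
  has_ilt <- ilt > 0
  structure(list(
    pws_kpa = field$stress_kpa[i_pws],
    pws_station = i_pws,
    pws_position = m$centerline$points[i_pws, ],
    pwri = field$rupture_index[i_pwri],
    pwri_station = i_pwri,
    pwri_position = m$centerline$points[i_pwri, ],
    mean_ilt_stress_kpa = if (any(has_ilt))
      mean(field$stress_kpa[has_ilt]) else NA_real_
  ), class = "biomech_metrics")
}

#' @export
print.biomech_metrics <- function(x, ...) {
  cat("<biomech_metrics> PWS", format(x$pws_kpa, digits = 4),
      "kPa @ station", x$pws_station,
      "| PWRI", format(x$pwri, digits = 4), "@ station",
      x$pwri_station, "\n")
  invisible(x)
}
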