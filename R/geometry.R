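#' Vessel centerline with anatomical stations
#'
#' An ordered 3-D polyline (mm) with a named map from anatomical
#' stations to point indices. The stations used by the morphometry are
#' `lowest_renal`, `neck_end`, `aaa_start`, `aortic_bifurcation` and
#' `inguinal_ligament`; the polyline may start proximal to
#' `lowest_renal` (the suprarenal segment needed for the alpha angle)
#' and extend through a common iliac artery to the inguinal ligament.
#'
#' @param points n x 3 numeric matrix, mm, ordered proximal to distal.
#' @param stations named integer vector of point indices.
#' @return Object of class `centerline`.
#' @export
centerline <- function(points, stations = integer()) {
  points <- as_xyz_matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("centerline needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (any(seg <= 0)) {
    stop("consecutive centerline points must be distinct (zero-length ",
         "segment at index ", which(seg <= 0)[1L], ")", call. = FALSE)
  }
  stations <- setNames(as.integer(stations), names(stations))
  if (length(stations)) {
    if (any(stations < 1L | stations > n)) {
      stop("station index out of range", call. = FALSE)
    }
    ana <- c("lowest_renal", "aortic_bifurcation", "inguinal_ligament")
    present <- ana[ana %in% names(stations)]
    if (length(present) > 1L && is.unsorted(stations[present])) {
      stop("stations out of anatomical order: ",
           paste(present, collapse = " -> "), call. = FALSE)
    }
  }
  structure(list(points = points, stations = stations,
                 arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline>", nrow(x$points), "points,",
      format(max(x$arclength), digits = 5), "mm arclength\n")
  if (length(x$stations)) {
    cat("  stations:", paste(names(x$stations), x$stations, sep = "=",
                             collapse = ", "), "\n")
  }
  invisible(x)
}

station_index <- function(cl, station) {
  if (!station %in% names(cl$stations)) {
    stop("centerline has no station '", station, "'", call. = FALSE)
  }
  cl$stations[[station]]
}

#' Total or per-point cumulative arclength of a centerline
#'
#' @param cl a [centerline()].
#' @param cumulative return the per-point cumulative arclength instead
#'   of the total.
#' @return numeric, mm.
#' @export
arc_length <- function(cl, cumulative = FALSE) {
  stopifnot(inherits(cl, "centerline"))
  if (cumulative) cl$arclength else max(cl$arclength)
}

#' Parametric vessel model: centerline plus radius profiles
#'
#' The lumen radius describes the flow channel, the outer radius the
#' outer vessel contour; their difference is the radial intraluminal
#' thrombus (ILT) thickness at each station. The wall itself is not
#' modelled separately: "vessel volume" is the volume inside the outer
#' contour, so ILT volume = vessel volume - lumen volume by definition.
#'
#' @param cl a [centerline()].
#' @param lumen_radius,outer_radius numeric vectors, one radius (mm) per
#'   centerline point, with `outer_radius >= lumen_radius >= 0`.
#' @return Object of class `vessel_model`.
#' @export
vessel_model <- function(cl, lumen_radius, outer_radius) {
  stopifnot(inherits(cl, "centerline"))
  n <- nrow(cl$points)
  lumen_radius <- as.numeric(lumen_radius)
  outer_radius <- as.numeric(outer_radius)
  stopifnot(length(lumen_radius) == n, length(outer_radius) == n,
            all(is.finite(lumen_radius)), all(is.finite(outer_radius)))
  if (any(lumen_radius < 0)) stop("negative lumen radius", call. = FALSE)
  if (any(outer_radius < lumen_radius - 1e-12)) {
    stop("outer radius below lumen radius at station ",
         which(outer_radius < lumen_radius - 1e-12)[1L], call. = FALSE)
  }
  structure(list(centerline = cl, lumen_radius = lumen_radius,
                 outer_radius = pmax(outer_radius, lumen_radius)),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat("<vessel_model>", nrow(x$centerline$points), "stations, max outer",
      "diameter", format(2 * max(x$outer_radius), digits = 4), "mm\n")
  invisible(x)
}

#' Tortuosity index between two stations
#'
#' Ratio of centerline arclength to straight-line ("raceline") distance
#' between two anatomical stations; 1 for a straight vessel. Aortic
#' tortuosity uses lowest renal artery to aortic bifurcation, iliac
#' tortuosity aortic bifurcation to inguinal ligament.
#'
#' @param cl a [centerline()].
#' @param from,to station names; `from` must be proximal to `to`.
#' @return dimensionless ratio >= 1 (up to discretisation error).
#' @export
tortuosity_index <- function(cl, from, to) {
  stopifnot(inherits(cl, "centerline"))
  i <- station_index(cl, from); j <- station_index(cl, to)
  if (i >= j) stop("station '", from, "' must precede '", to, "'",
                   call. = FALSE)
  race <- sqrt(sum((cl$points[j, ] - cl$points[i, ])^2))
  if (race <= 0) {
    stop("zero straight-line distance between stations '", from,
         "' and '", to, "'", call. = FALSE)
  }
  (cl$arclength[j] - cl$arclength[i]) / race
}

#' Maximum diameter of the lumen or outer contour
#'
#' Diameter is twice the selected radius profile's maximum; ties are
#' broken toward the proximal (smallest-index) station with a message.
#'
#' @param m a [vessel_model()].
#' @param use `"outer"` (default) or `"lumen"` profile.
#' @return list `diameter_mm`, `station`.
#' @export
max_diameter <- function(m, use = c("outer", "lumen")) {
  stopifnot(inherits(m, "vessel_model"))
  use <- match.arg(use)
  r <- if (use == "outer") m$outer_radius else m$lumen_radius
  idx <- which(r == max(r))
  if (length(idx) > 1L) {
    message("max_diameter: ", length(idx),
            " tied maxima; proximal station ", idx[1L], " reported")
  }
  list(diameter_mm = 2 * r[idx[1L]], station = idx[1L])
}

#' Maximum radial ILT thickness
#'
#' ILT thickness is defined radially per station as outer minus lumen
#' radius. Returns the maximum, its station, and the station's 3-D
#' point (the `max_ilt` landmark exported for registration).
#'
#' @param m a [vessel_model()].
#' @return list `thickness_mm`, `station`, `position` (length-3, mm).
#' @export
max_ilt_thickness <- function(m) {
  stopifnot(inherits(m, "vessel_model"))
  th <- m$outer_radius - m$lumen_radius
  idx <- which(th == max(th))
  if (length(idx) > 1L && max(th) > 0) {
    message("max_ilt_thickness: ", length(idx),
            " tied maxima; proximal station ", idx[1L], " reported")
  }
  list(thickness_mm = th[idx[1L]], station = idx[1L],
       position = m$centerline$points[idx[1L], ])
}

mean_tangent <- function(cl, s_from, s_to) {
  s <- cl$arclength
  n <- nrow(cl$points)
  seg_from <- s[-n]; seg_to <- s[-1L]
  # segments overlapping [s_from, s_to], weighted by overlapped length
  w <- pmax(0, pmin(seg_to, s_to) - pmax(seg_from, s_from))
  if (sum(w > 0) < 1L) {
    stop("tangent window [", format(s_from), ", ", format(s_to),
         "] mm covers fewer than one centerline segment", call. = FALSE)
  }
  dirs <- cl$points[-1L, , drop = FALSE] - cl$points[-n, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  v <- colSums(dirs * w)
  nv <- sqrt(sum(v^2))
  if (nv <= 0) stop("degenerate mean tangent", call. = FALSE)
  v / nv
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Suprarenal-to-neck (alpha) and neck-to-AAA (beta) angulation
#'
#' Angles between mean unit tangents averaged over fixed-arclength
#' windows: alpha between the suprarenal segment just proximal to the
#' lowest renal artery and the first part of the infrarenal neck; beta
#' between the distal neck and the proximal aneurysm segment. Mean
#' tangents over windows (default 15 mm) are used instead of two-point
#' chords for robustness to sampling density.
#'
#' @param cl a [centerline()] with stations `lowest_renal`, `neck_end`
#'   and `aaa_start`, and points proximal to `lowest_renal`.
#' @param window_mm tangent-averaging window, mm.
#' @return list `alpha_deg`, `beta_deg`, both in `[0, 180)`.
#' @export
neck_angles <- function(cl, window_mm = 15) {
  stopifnot(inherits(cl, "centerline"), window_mm > 0)
  s <- cl$arclength
  s_lr <- s[station_index(cl, "lowest_renal")]
  s_ne <- s[station_index(cl, "neck_end")]
  s_as <- s[station_index(cl, "aaa_start")]
  if (s_as < s_ne) stop("aaa_start precedes neck_end", call. = FALSE)
  t_supra <- mean_tangent(cl, max(0, s_lr - window_mm), s_lr)
  t_neck_prox <- mean_tangent(cl, s_lr, min(s_ne, s_lr + window_mm))
  t_neck_dist <- mean_tangent(cl, max(s_lr, s_ne - window_mm), s_ne)
  t_aaa <- mean_tangent(cl, s_as, min(max(s), s_as + window_mm))
  list(alpha_deg = angle_deg(t_supra, t_neck_prox),
       beta_deg = angle_deg(t_neck_dist, t_aaa))
}

#' Lumen, vessel and ILT volumes
#'
#' Volumes by conical-frustum integration of the radius profiles along
#' the centerline: each consecutive station pair contributes
#' `pi/3 * h * (r1^2 + r1*r2 + r2^2)` with `h` the segment length.
#' Vessel volume integrates the outer profile; ILT volume is vessel
#' minus lumen, so additivity is exact by construction.
#'
#' @param m a [vessel_model()].
#' @return list `lumen_mm3`, `vessel_mm3`, `ilt_mm3`.
#' @export
vessel_volumes <- function(m) {
  stopifnot(inherits(m, "vessel_model"))
  h <- diff(m$centerline$arclength)
  frustum <- function(r) {
    n <- length(r)
    sum(pi / 3 * h * (r[-n]^2 + r[-n] * r[-1L] + r[-1L]^2))
  }
  lumen <- frustum(m$lumen_radius)
  vessel <- frustum(m$outer_radius)
  list(lumen_mm3 = lumen, vessel_mm3 = vessel, ilt_mm3 = vessel - lumen)
}

#' Neck length and diameter
#'
#' Neck length is the centerline arclength from the lowest renal artery
#' to the beginning of the aneurysm; neck diameter is twice the outer
#' radius at the lowest renal artery.
#'
#' @param m a [vessel_model()] whose centerline carries stations
#'   `lowest_renal` and `aaa_start`.
#' @return list `neck_length_mm`, `neck_diameter_mm`.
#' @export
neck_measures <- function(m) {
  stopifnot(inherits(m, "vessel_model"))
  cl <- m$centerline
  i <- station_index(cl, "lowest_renal")
  j <- station_index(cl, "aaa_start")
  if (j < i) stop("aaa_start precedes lowest_renal", call. = FALSE)
  list(neck_length_mm = cl$arclength[j] - cl$arclength[i],
       neck_diameter_mm = 2 * m$outer_radius[i])
}

#' All geometric metrics of one vessel model
#'
#' Convenience wrapper collecting maximum outer and lumen diameters,
#' maximum ILT thickness, neck angles and measures, aortic and iliac
#' tortuosity indices and the three volumes into one row. Iliac
#' tortuosity needs stations `aortic_bifurcation` and
#' `inguinal_ligament`; when absent it is reported `NA` (never imputed).
#'
#' @param m a [vessel_model()].
#' @param angle_window_mm tangent window for [neck_angles()].
#' @return one-row data.frame of metrics.
#' @export
geometric_metrics <- function(m, angle_window_mm = 15) {
  stopifnot(inherits(m, "vessel_model"))
  cl <- m$centerline
  dmax <- max_diameter(m, "outer")
  dlum <- max_diameter(m, "lumen")
  ilt <- max_ilt_thickness(m)
  ang <- neck_angles(cl, angle_window_mm)
  nm <- neck_measures(m)
  vol <- vessel_volumes(m)
  has <- function(st) st %in% names(cl$stations)
  aortic <- if (has("lowest_renal") && has("aortic_bifurcation")) {
    tortuosity_index(cl, "lowest_renal", "aortic_bifurcation")
  } else NA_real_
  iliac <- if (has("aortic_bifurcation") && has("inguinal_ligament")) {
    tortuosity_index(cl, "aortic_bifurcation", "inguinal_ligament")
  } else NA_real_
  data.frame(
    aaa_diameter_mm = dmax$diameter_mm,
    max_lumen_diameter_mm = dlum$diameter_mm,
    max_ilt_thickness_mm = ilt$thickness_mm,
    alpha_angle_deg = ang$alpha_deg,
    beta_angle_deg = ang$beta_deg,
    neck_length_mm = nm$neck_length_mm,
    neck_diameter_mm = nm$neck_diameter_mm,
    aortic_tortuosity = aortic,
    iliac_tortuosity = iliac,
    lumen_volume_cm3 = vol$lumen_mm3 / 1000,
    vessel_volume_cm3 = vol$vessel_mm3 / 1000,
    ilt_volume_cm3 = vol$ilt_mm3 / 1000
  )
}
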