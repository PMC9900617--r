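#' Log-normal parameters from a median and quartiles
#'
#' Solves `meanlog = log(median)` and `sdlog = (log(q3) - log(q1)) /
#' (2 * qnorm(0.75))`, the log-normal whose median matches exactly and
#' whose interquartile range matches the configured quartile ratio.
#'
#' @param median,q1,q3 positive values with `q1 <= median <= q3`.
#' @return list `meanlog`, `sdlog`.
#' @export
lnorm_from_quartiles <- function(median, q1, q3) {
  stopifnot(q1 > 0, q3 >= q1, median >= q1, median <= q3)
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

# CT1 baseline distributions and change distributions emulating a
# surveillance cohort of infrarenal AAA under open-repair workup
# (median diameter ~50 mm at first CT). Multiplicative variables use
# log-normal growth factors (median / quartiles of the factor),
# additive variables Gaussian absolute changes.
cohort_defaults <- function() {
  base <- list( # median, q1, q3 of CT1 value
    aaa_diameter_mm      = c(49.9, 45.8, 52.0),
    alpha_angle_deg      = c(14.8, 10.9, 20.7),
    beta_angle_deg       = c(28.7, 21.5, 33.7),
    neck_length_mm       = c(20.5, 9.0, 37.5),
    neck_diameter_mm     = c(24.0, 22.0, 27.68),
    aortic_tortuosity    = c(1.07, 1.06, 1.12),
    iliac_tortuosity     = c(1.30, 1.21, 1.36),
    max_lumen_diameter_mm = c(37.0, 32.4, 41.6),
    max_ilt_thickness_mm = c(14.0, 9.0, 20.0),
    lumen_volume_cm3     = c(68, 48, 82),
    vessel_volume_cm3    = c(129, 93, 164),
    ilt_volume_cm3       = c(37, 26, 64),
    pws_kpa              = c(190, 156, 229),
    pwri                 = c(0.36, 0.33, 0.42)
  )
  mult <- list( # percent change: median, q1, q3
    max_lumen_diameter_mm = c(13, 4, 20),
    max_ilt_thickness_mm = c(35, 5, 61),
    lumen_volume_cm3     = c(18, 4, 40),
    vessel_volume_cm3    = c(17, 13, 38),
    ilt_volume_cm3       = c(43, 16, 81),
    pws_kpa              = c(12, 1, 23),
    pwri                 = c(16, 0, 24)
  )
  add <- list( # absolute change: median, q1, q3
    alpha_angle_deg   = c(0.5, -1.5, 6.2),
    beta_angle_deg    = c(2.9, -1.8, 5.9),
    neck_length_mm    = c(-0.5, -4.5, 3.8),
    neck_diameter_mm  = c(-0.9, -1.8, 1.0),
    aortic_tortuosity = c(0.002, -0.006, 0.022),
    iliac_tortuosity  = c(0.016, -0.012, 0.045)
  )
  # loadings of each change variable's latent normal on the shared
  # vessel-volume latent (pws/pwri loadings are calibrated separately)
  loadings <- c(lumen_volume_cm3 = 0.5, ilt_volume_cm3 = 0.6,
                max_ilt_thickness_mm = 0.5, max_lumen_diameter_mm = 0.4,
                growth_rate = 0.3)
  list(base = base, mult = mult, add = add, loadings = loadings)
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Pearson correlation of absolute deltas induced by latent correlation
# `rho` between the log-change normals, given log-normal baselines and
# growth factors. Deterministic (internal fixed seed), common random
# numbers across rho so the map is smooth and monotone.
induced_delta_cor <- function(rho, base_x, base_y, lg_x, lg_y,
                              n = 200000L) {
  zv <- rnorm(n); e <- rnorm(n)
  bx <- rlnorm(n, log(base_x[1L]),
               (log(base_x[3L]) - log(base_x[2L])) / (2 * qnorm(0.75)))
  by <- rlnorm(n, log(base_y[1L]),
               (log(base_y[3L]) - log(base_y[2L])) / (2 * qnorm(0.75)))
  fx <- exp(lg_x$meanlog + lg_x$sdlog * zv)
  dy_of <- function(r) {
    zy <- r * zv + sqrt(1 - r^2) * e
    by * (exp(lg_y$meanlog + lg_y$sdlog * zy) - 1)
  }
  dx <- bx * (fx - 1)
  function(r) stats::cor(dx, dy_of(r))
}

calibrate_latent_rho <- function(target, base_x, base_y, lg_x, lg_y) {
  if (abs(target) < 1e-12) return(0)
  s <- sign(target); target <- abs(target)
  r_latent <- with_preserved_rng({
    set.seed(20260901L)
    f <- induced_delta_cor(target, base_x, base_y, lg_x, lg_y)
    if (f(0.999) < target) {
      stop("requested change-correlation ", s * target,
           " is infeasible under the configured baseline variability",
           call. = FALSE)
    }
    stats::uniroot(function(r) f(r) - target, c(0, 0.999),
                   tol = 1e-4)$root
  })
  s * r_latent
}

#' Specification of a synthetic paired-timepoint AAA cohort
#'
#' Defines the study conditions emulated by the generator: cohort size,
#' surveillance interval, diameter growth rate (log-normal, median
#' 3.7 mm/year, IQR 2.25–5.44), landmark digitisation noise
#' (isotropic Gaussian, default sd 1.5 mm — the scale of sub-2.5 mm CT
#' slice spacing), the target Pearson correlations between the absolute
#' vessel-volume change and the PWS / PWRI changes (defaults 0.68 and
#' 0.60), the distribution of true maximum-point surface motions
#' (log-normal, median 10 mm, drawn independently of every geometric
#' change), and the planted inter-timepoint transform family.
#'
#' Because baselines and growth factors are log-normal, the Pearson
#' correlation of the absolute deltas is attenuated relative to the
#' latent Gaussian-copula correlation on log-changes; the constructor
#' therefore calibrates the latent correlation once (deterministic
#' internal Monte-Carlo) so that the *induced* delta correlation meets
#' the requested target.
#'
#' @param n_patients cohort size (>= 1).
#' @param seed global integer seed; per-patient seeds are derived from
#'   it so generation is reproducible patient by patient.
#' @param interval_months_range uniform range of CT1–CT2 interval.
#' @param growth_rate list `median`, `q1`, `q3` of the annual diameter
#'   growth rate, mm/year.
#' @param landmark_noise_sd isotropic landmark noise sd, mm.
#' @param rho_pws,rho_pwri target Pearson correlation between absolute
#'   vessel-volume change and absolute PWS / PWRI change; `|rho| < 1`.
#' @param motion_spec either `list(type = "lognormal", median_mm,
#'   sdlog)` or `list(type = "fixed", values_mm = c(ilt, pws, pwri))`.
#' @param transform_spec list `mode` (`"rigid"`, `"similarity"`,
#'   `"affine"`), `max_rotation_deg`, `max_translation_mm`, `shear`
#'   (affine perturbation half-range), `scale_range` (similarity).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 32L, seed = 1L,
                        interval_months_range = c(6, 24),
                        growth_rate = list(median = 3.7, q1 = 2.25,
                                           q3 = 5.44),
                        landmark_noise_sd = 1.5,
                        rho_pws = 0.68, rho_pwri = 0.60,
                        motion_spec = list(type = "lognormal",
                                           median_mm = 10, sdlog = 0.6),
                        transform_spec = list(mode = "affine",
                                              max_rotation_deg = 10,
                                              max_translation_mm = 30,
                                              shear = 0.03,
                                              scale_range = c(0.95, 1.05))) {
  stopifnot(n_patients >= 1L, landmark_noise_sd >= 0,
            abs(rho_pws) < 1, abs(rho_pwri) < 1,
            interval_months_range[1L] > 0,
            interval_months_range[2L] >= interval_months_range[1L])
  defs <- cohort_defaults()
  growth_lnorm <- lnorm_from_quartiles(growth_rate$median, growth_rate$q1,
                                       growth_rate$q3)
  lg <- function(var) {
    p <- defs$mult[[var]]
    lnorm_from_quartiles(1 + p[1L] / 100, 1 + p[2L] / 100, 1 + p[3L] / 100)
  }
  lat_pws <- calibrate_latent_rho(rho_pws, defs$base$vessel_volume_cm3,
                                  defs$base$pws_kpa,
                                  lg("vessel_volume_cm3"), lg("pws_kpa"))
  lat_pwri <- calibrate_latent_rho(rho_pwri, defs$base$vessel_volume_cm3,
                                   defs$base$pwri,
                                   lg("vessel_volume_cm3"), lg("pwri"))
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    interval_months_range = interval_months_range,
    growth_rate = growth_rate, growth_lnorm = growth_lnorm,
    landmark_noise_sd = landmark_noise_sd,
    rho_pws = rho_pws, rho_pwri = rho_pwri,
    latent_rho_pws = lat_pws, latent_rho_pwri = lat_pwri,
    motion_spec = motion_spec, transform_spec = transform_spec,
    defaults = defs
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  growth median", x$growth_rate$median, "mm/y; noise sd",
      x$landmark_noise_sd, "mm; rho(vol,PWS)", x$rho_pws,
      "(latent", round(x$latent_rho_pws, 3), ")\n")
  invisible(x)
}

# splitmix-style per-patient seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 30269) %%
               2147483563) + 1L
}

unit <- function(v) v / sqrt(sum(v^2))

# random axis-angle rotation with angle <= max_deg
random_rotation <- function(max_deg) {
  ax <- unit(rnorm(3))
  th <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_planted_transform <- function(tspec) {
  R <- random_rotation(tspec$max_rotation_deg)
  tr <- runif(3, -tspec$max_translation_mm, tspec$max_translation_mm)
  A <- switch(tspec$mode,
    rigid = R,
    similarity = runif(1, tspec$scale_range[1L], tspec$scale_range[2L]) * R,
    affine = {
      E <- matrix(runif(9, -tspec$shear, tspec$shear), 3L, 3L)
      M <- R %*% (diag(3) + E)
      if (det(M) < 0.5 || det(M) > 2) M <- R  # keep within sane volume change
      M
    },
    stop("unknown transform mode '", tspec$mode, "'"))
  linear_transform(A, tr, tspec$mode)
}

# two unit vectors orthogonal to t (and to each other)
orthonormal_frame <- function(t) {
  t <- unit(t)
  ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- unit(ref - sum(ref * t) * t)
  n2 <- pracma_cross(t, n1)
  list(n1 = n1, n2 = n2)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# ---------------------------------------------------------------------
# synthetic vessel construction

# Build an abdominal aortic centerline with planted neck angulation and
# mild curvature, 1 mm sampling: suprarenal start at s=0, lowest renal
# at 20 mm, neck of the requested length, fusiform sac, aortic
# bifurcation at 150 mm, left common iliac to the inguinal ligament at
# 220 mm.
build_synthetic_vessel <- function(d_max_mm, ilt_max_mm, neck_length_mm,
                                   alpha_deg, beta_deg, azimuths,
                                   curvature_amp_mm = 4,
                                   ilt_peak_offset_mm = 8) {
  ds <- 1
  s_lr <- 20; s_bif <- 150; s_end <- 220
  neck_length_mm <- min(max(neck_length_mm, 4), 40)
  s_as <- s_lr + neck_length_mm
  s_bulge <- s_as + 45
  w <- 16
  s <- seq(0, s_end, by = ds)
  n <- length(s)
  rot_about <- function(v, axis, deg) {
    th <- deg * pi / 180; axis <- unit(axis)
    v * cos(th) + pracma_cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  }
  d0 <- c(0, 0, -1)
  f0 <- orthonormal_frame(d0)
  ax1 <- unit(cos(azimuths[1L]) * f0$n1 + sin(azimuths[1L]) * f0$n2)
  d_neck <- rot_about(d0, ax1, alpha_deg)
  ax2 <- unit(cos(azimuths[2L]) * f0$n1 + sin(azimuths[2L]) * f0$n2)
  d_aaa <- rot_about(d_neck, ax2, beta_deg)
  blend <- function(si, s0, width = 8) pmin(1, pmax(0, (si - s0) / width))
  # sinusoidal tangent tilt gives realistic tortuosity: mild along the
  # aorta, pronounced along the common iliac (indices ~1.07 / ~1.3)
  b_il <- blend(s, s_bif, 15)
  tilt <- (1 - b_il) * 0.35 * sin(2 * pi * s / 90) +
    b_il * 0.85 * sin(2 * pi * (s - s_bif) / 55)
  psi <- 2 * pi * s / 180
  pts <- matrix(0, n, 3L)
  for (i in 2:n) {
    b1 <- blend(s[i], s_lr); b2 <- blend(s[i], s_as)
    base <- (1 - b1) * d0 + b1 * ((1 - b2) * d_neck + b2 * d_aaa)
    dir <- unit(unit(base) +
                  tilt[i] * (cos(psi[i]) * f0$n1 + sin(psi[i]) * f0$n2))
    pts[i, ] <- pts[i - 1L, ] + ds * dir
  }
  bow <- curvature_amp_mm * sin(pi * s / s_end)^2
  pts[, 1L] <- pts[, 1L] + bow
  r_aorta <- 11; r_iliac <- 7
  taper <- pmin(1, pmax(0, (s - s_bif) / 12))
  lumen_base <- r_aorta + (r_iliac - r_aorta) * taper
  amp <- max(d_max_mm / 2 - r_aorta, 0)
  bulge <- amp * exp(-(s - s_bulge)^2 / (2 * w^2))
  outer <- lumen_base + bulge
  ilt <- pmin(ilt_max_mm, bulge + 2) *
    exp(-(s - (s_bulge + ilt_peak_offset_mm))^2 / (2 * w^2))
  lumen <- pmax(outer - ilt, pmin(lumen_base, 5))
  idx_of <- function(sv) which.min(abs(s - sv))
  cl <- centerline(pts, stations = c(
    lowest_renal = idx_of(s_lr), neck_end = idx_of(s_as),
    aaa_start = idx_of(s_as), aortic_bifurcation = idx_of(s_bif),
    inguinal_ligament = n))
  vessel_model(cl, lumen, outer)
}

surface_point <- function(m, station, azimuth) {
  cl <- m$centerline
  n <- nrow(cl$points)
  i0 <- max(1L, station - 1L); i1 <- min(n, station + 1L)
  t <- unit(cl$points[i1, ] - cl$points[i0, ])
  f <- orthonormal_frame(t)
  radial <- cos(azimuth) * f$n1 + sin(azimuth) * f$n2
  list(point = cl$points[station, ] + m$outer_radius[station] * radial,
       tangent = t, circumferential = pracma_cross(t, radial))
}

draw_motions <- function(mspec) {
  if (mspec$type == "fixed") {
    v <- rep_len(as.numeric(mspec$values_mm), 3L)
  } else if (mspec$type == "lognormal") {
    v <- rlnorm(3L, log(mspec$median_mm), mspec$sdlog)
  } else stop("unknown motion_spec type '", mspec$type, "'")
  setNames(v, c("max_ilt", "max_pws", "max_pwri"))
}

# draws the ground-truth record row for one patient as a named numeric
# vector (fast path); consumes RNG in a fixed order shared with
# simulate_patient()
draw_patient_vector <- function(spec) {
  defs <- spec$defaults
  interval <- runif(1, spec$interval_months_range[1L],
                    spec$interval_months_range[2L])
  age <- round(rnorm(1, 70, 8))
  z_vol <- rnorm(1)
  lat <- function(load) load * z_vol + sqrt(1 - load^2) * rnorm(1)
  z <- c(vessel_volume_cm3 = z_vol,
         pws_kpa = lat(spec$latent_rho_pws),
         pwri = lat(spec$latent_rho_pwri),
         lumen_volume_cm3 = lat(defs$loadings[["lumen_volume_cm3"]]),
         ilt_volume_cm3 = lat(defs$loadings[["ilt_volume_cm3"]]),
         max_ilt_thickness_mm = lat(defs$loadings[["max_ilt_thickness_mm"]]),
         max_lumen_diameter_mm = lat(defs$loadings[["max_lumen_diameter_mm"]]),
         growth_rate = lat(defs$loadings[["growth_rate"]]))
  growth_rate <- exp(spec$growth_lnorm$meanlog +
                       spec$growth_lnorm$sdlog * z[["growth_rate"]])
  row <- c(interval_months = interval, age_at_operation = age)
  draw_base <- function(var) {
    p <- defs$base[[var]]
    ln <- lnorm_from_quartiles(p[1L], p[2L], p[3L])
    rlnorm(1, ln$meanlog, ln$sdlog)
  }
  for (var in names(defs$base)) {
    ct1 <- if (var %in% c("alpha_angle_deg", "beta_angle_deg")) {
      p <- defs$base[[var]]
      rnorm(1, p[1L], (p[3L] - p[2L]) / (2 * qnorm(0.75)))
    } else draw_base(var)
    ct2 <- if (var == "aaa_diameter_mm") {
      ct1 + growth_rate * interval / 12
    } else if (var %in% names(defs$mult)) {
      p <- defs$mult[[var]]
      ln <- lnorm_from_quartiles(1 + p[1L] / 100, 1 + p[2L] / 100,
                                 1 + p[3L] / 100)
      zv <- if (var %in% names(z)) z[[var]] else rnorm(1)
      ct1 * exp(ln$meanlog + ln$sdlog * zv)
    } else {
      p <- defs$add[[var]]
      ct1 + rnorm(1, p[1L], (p[3L] - p[2L]) / (2 * qnorm(0.75)))
    }
    row[paste0(var, c("_ct1", "_ct2"))] <- c(ct1, ct2)
  }
  motions <- draw_motions(spec$motion_spec)
  row[c("motion_max_ilt_mm", "motion_max_pws_mm", "motion_max_pwri_mm")] <-
    motions[c("max_ilt", "max_pws", "max_pwri")]
  row[["growth_rate_mm_per_year"]] <- growth_rate
  row
}

draw_patient_record <- function(spec, patient_id) {
  row <- as.data.frame(as.list(draw_patient_vector(spec)))
  cbind(data.frame(patient_id = patient_id), row)
}

#' Simulate one synthetic paired-timepoint patient
#'
#' Draws the patient's ground-truth record (interval, growth, correlated
#' metric changes, independent max-point motions), then materialises:
#' a CT1 vessel model (fusiform bulge on a curved, angulated
#' centerline), a CT2 model grown per the drawn diameter growth and
#' mapped through a planted linear transform, and the two landmark sets
#' — 9 anatomically placed fit landmarks, 1 validation landmark
#' (inferior mesenteric artery level) and 3 maximum points located from
#' the CT1 model's own geometry and stress surrogate. CT2 fit and
#' validation landmarks are the planted transform applied to CT1 plus
#' isotropic Gaussian noise; each CT2 maximum point is the transformed
#' CT1 point plus a vector of exactly the planted motion magnitude,
#' tangent to the local surface, so true motion never aliases into pure
#' growth.
#'
#' @param spec a [cohort_spec()].
#' @param patient_seed integer; together with `spec$seed` it fully
#'   determines the patient.
#' @param patient_id identifier (default derived from `patient_seed`).
#' @return Object of class `synthetic_patient` with elements `ct1`,
#'   `ct2` ([landmark_set()]s), `model_ct1`, `model_ct2`
#'   ([vessel_model()]s), `transform` (planted [linear_transform()]),
#'   `motions_mm` (named length-3), `interval_months`, `record`
#'   (one-row ground-truth data.frame).
#' @export
simulate_patient <- function(spec, patient_seed,
                             patient_id = sprintf("P%03d", patient_seed)) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, patient_seed))
  record <- draw_patient_record(spec, patient_id)
  record$patient_id <- patient_id

  # geometry realising the drawn CT1 diameter / ILT / neck / angles
  alpha <- max(record$alpha_angle_deg_ct1, 2)
  beta <- max(record$beta_angle_deg_ct1, 2)
  azim <- runif(3, 0, 2 * pi)
  d1 <- record$aaa_diameter_mm_ct1
  ilt1 <- min(record$max_ilt_thickness_mm_ct1, d1 / 2 - 6)
  m1 <- build_synthetic_vessel(d1, ilt1, record$neck_length_mm_ct1,
                               alpha, beta, azim[1:2])
  d2 <- record$aaa_diameter_mm_ct2
  ilt2 <- min(ilt1 * record$max_ilt_thickness_mm_ct2 /
                record$max_ilt_thickness_mm_ct1, d2 / 2 - 5)
  m2_shape <- build_synthetic_vessel(d2, ilt2, record$neck_length_mm_ct2,
                                     alpha, max(record$beta_angle_deg_ct2, 2),
                                     azim[1:2])
  planted <- random_planted_transform(spec$transform_spec)
  cl2 <- centerline(apply_transform(planted, m2_shape$centerline$points),
                    m2_shape$centerline$stations)
  m2 <- vessel_model(cl2, m2_shape$lumen_radius, m2_shape$outer_radius)

  # maximum points from the CT1 model's own metrics
  sf1 <- stress_field(m1)
  bm1 <- biomech_metrics(sf1, m1)
  ilt_pk <- max_ilt_thickness(m1)
  max_az <- runif(3, 0, 2 * pi)
  sp_ilt <- surface_point(m1, ilt_pk$station, max_az[1L])
  sp_pws <- surface_point(m1, bm1$pws_station, max_az[2L])
  sp_pwri <- surface_point(m1, bm1$pwri_station, max_az[3L])
  max_src <- rbind(max_ilt = sp_ilt$point, max_pws = sp_pws$point,
                   max_pwri = sp_pwri$point)

  # fit + validation landmarks at anatomical offsets from the centerline
  cl1 <- m1$centerline
  off_pt <- function(s_idx, dir, dist) cl1$points[s_idx, ] + dist * unit(dir)
  frame_at <- function(s_idx) {
    n <- nrow(cl1$points)
    orthonormal_frame(cl1$points[min(n, s_idx + 1L), ] -
                        cl1$points[max(1L, s_idx - 1L), ])
  }
  f20 <- frame_at(21L); f5 <- frame_at(6L); f150 <- frame_at(151L)
  f165 <- frame_at(166L); f120 <- frame_at(121L)
  fit_src <- rbind(
    sma = off_pt(6L, f5$n1, 12),
    left_renal = off_pt(21L, f20$n2, 15),
    right_renal = off_pt(21L, -f20$n2, 15),
    lumbar_1 = off_pt(61L, -frame_at(61L)$n1, 12),
    lumbar_2 = off_pt(81L, -frame_at(81L)$n1, 12),
    lumbar_3 = off_pt(101L, -frame_at(101L)$n1, 12),
    aortic_bifurcation = cl1$points[151L, ],
    left_cia = off_pt(166L, f165$n2, 8),
    right_cia = off_pt(166L, -f165$n2, 8))
  val_src <- off_pt(121L, f120$n1, 10)

  sdn <- spec$landmark_noise_sd
  noise <- function(k) matrix(rnorm(3L * k, 0, sdn), k, 3L)
  fit_tgt <- apply_transform(planted, fit_src) + noise(nrow(fit_src))
  val_tgt <- apply_transform(planted, val_src) + as.numeric(noise(1L))

  motions <- c(max_ilt = record$motion_max_ilt_mm,
               max_pws = record$motion_max_pws_mm,
               max_pwri = record$motion_max_pwri_mm)
  tangent_of <- list(max_ilt = sp_ilt, max_pws = sp_pws, max_pwri = sp_pwri)
  max_tgt <- max_src * NA_real_
  phi <- runif(3, 0, 2 * pi)
  for (k in seq_len(3L)) {
    sp <- tangent_of[[k]]
    u <- cos(phi[k]) * sp$tangent + sin(phi[k]) * sp$circumferential
    v <- unit(as.numeric(planted$matrix %*% u))
    max_tgt[k, ] <- apply_transform(planted, max_src[k, ]) +
      motions[[rownames(max_src)[k]]] * v
  }

  mk_set <- function(tp, fit, val, mx) {
    landmark_set(patient_id, tp, data.frame(
      label = c(rownames(fit_src), "validation", rownames(max_src)),
      role = c(rep("fit", nrow(fit_src)), "validation",
               rep("maxpoint", nrow(max_src))),
      x_mm = c(fit[, 1L], val[1L], mx[, 1L]),
      y_mm = c(fit[, 2L], val[2L], mx[, 2L]),
      z_mm = c(fit[, 3L], val[3L], mx[, 3L])))
  }
  structure(list(
    patient_id = patient_id,
    ct1 = mk_set("ct1", fit_src, val_src, max_src),
    ct2 = mk_set("ct2", fit_tgt, val_tgt, max_tgt),
    model_ct1 = m1, model_ct2 = m2,
    transform = planted,
    motions_mm = motions,
    interval_months = record$interval_months,
    record = record
  ), class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient>", x$patient_id, "- interval",
      round(x$interval_months, 1), "months, planted motions (mm):",
      paste(round(x$motions_mm, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a paired-timepoint cohort
#'
#' Generates `spec$n_patients` synthetic patients (see
#' [simulate_patient()]) and the cohort ground-truth record table. Per
#' patient, the metric changes are drawn from a joint log-change
#' distribution whose induced Pearson correlations between the absolute
#' vessel-volume change and the PWS / PWRI changes meet the spec's
#' targets; max-point motions are drawn independently of all changes.
#'
#' @param spec a [cohort_spec()].
#' @param records_only skip the geometric/landmark materialisation and
#'   return only the ground-truth record table (fast path for
#'   statistical calibration studies). Record values are identical
#'   either way because record draws precede geometry draws.
#' @return Object of class `synthetic_cohort`: `patients` (list of
#'   [simulate_patient()] results, or `NULL`), `records` (data.frame),
#'   `spec`.
#' @export
simulate_cohort <- function(spec, records_only = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_patients == 1L) {
    warning("single-patient cohort: no correlation structure can be ",
            "realised or estimated", call. = FALSE)
  }
  patients <- if (records_only) NULL else vector("list", spec$n_patients)
  records <- vector("list", spec$n_patients)
  ids <- sprintf("P%03d", seq_len(spec$n_patients))
  if (records_only) {
    for (i in seq_len(spec$n_patients)) {
      set.seed(derive_seed(spec$seed, i))
      records[[i]] <- draw_patient_vector(spec)
    }
    records <- cbind(data.frame(patient_id = ids),
                     as.data.frame(do.call(rbind, records)))
  } else {
    for (i in seq_len(spec$n_patients)) {
      p <- simulate_patient(spec, i, ids[i])
      patients[[i]] <- p
      records[[i]] <- p$record
    }
    records <- do.call(rbind, records)
    rownames(records) <- NULL
  }
  structure(list(patients = patients, records = records, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$records), "patients",
      if (is.null(x$patients)) "(records only)" else "", "\n")
  invisible(x)
}

#' Simulate a single landmark correspondence set with a planted
#' transform
#'
#' Lightweight generator for registration studies: draws source fit
#' landmarks in a realistic abdominal field of view (roughly 160 x 160
#' x 220 mm), plants a random transform of the requested family,
#' produces targets as transform(source) plus isotropic noise, plus one
#' validation pair and up to three maximum-point pairs with exact
#' planted motion magnitudes.
#'
#' @param n_fit number of fit pairs (3–9).
#' @param mode planted transform family.
#' @param noise_sd isotropic target noise sd, mm.
#' @param motions_mm numeric vector (length <= 3) of planted
#'   maximum-point motion magnitudes.
#' @param transform_spec see [cohort_spec()].
#' @return list `corr` ([correspondence_set()]) and `transform` (the
#'   planted [linear_transform()]).
#' @export
simulate_correspondences <- function(n_fit = 9L,
                                     mode = c("affine", "similarity",
                                              "rigid"),
                                     noise_sd = 0,
                                     motions_mm = c(0, 5, 15),
                                     transform_spec = NULL) {
  mode <- match.arg(mode)
  if (is.null(transform_spec)) {
    transform_spec <- list(mode = mode, max_rotation_deg = 20,
                           max_translation_mm = 50, shear = 0.05,
                           scale_range = c(0.9, 1.1))
  }
  transform_spec$mode <- mode
  repeat {
    src <- cbind(runif(n_fit, -80, 80), runif(n_fit, -80, 80),
                 runif(n_fit, -110, 110))
    ok <- tryCatch({
      centered_condition(sweep(src, 2L, colMeans(src)), "affine") < 1e4
    }, error = function(e) FALSE)
    if (isTRUE(ok)) break
  }
  planted <- random_planted_transform(transform_spec)
  tgt <- apply_transform(planted, src) +
    matrix(rnorm(3L * n_fit, 0, noise_sd), n_fit, 3L)
  val_src <- c(runif(2, -40, 40), runif(1, -80, 80))
  val_tgt <- apply_transform(planted, val_src) + rnorm(3L, 0, noise_sd)
  k <- length(motions_mm)
  labels <- c("max_ilt", "max_pws", "max_pwri")[seq_len(k)]
  max_src <- cbind(runif(k, -30, 30), runif(k, -30, 30), runif(k, -60, 60))
  max_tgt <- apply_transform(planted, max_src)
  for (j in seq_len(k)) {
    max_tgt[j, ] <- max_tgt[j, ] + motions_mm[j] * unit(rnorm(3L))
  }
  corr <- correspondence_set(
    patient_id = "sim",
    fit_source = src, fit_target = tgt,
    fit_labels = paste0("fix_", seq_len(n_fit)),
    validation_source = val_src, validation_target = val_tgt,
    validation_label = "validation",
    maxpoint_source = max_src, maxpoint_target = max_tgt,
    maxpoint_labels = labels)
  list(corr = corr, transform = planted)
}
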