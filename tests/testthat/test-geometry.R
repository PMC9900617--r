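test_that("tortuosity is 1 for a straight vessel and pi/2 for a semicircle", {
  m <- straight_tube(stations = c(lowest_renal = 10,
                                  aortic_bifurcation = 90))
  expect_identical(tortuosity_index(m$centerline, "lowest_renal",
                                    "aortic_bifurcation"), 1)
  th <- seq(0, pi, length.out = 1000)
  arc <- centerline(cbind(50 * cos(th), 50 * sin(th), 0),
                    stations = c(lowest_renal = 1,
                                 aortic_bifurcation = 1000))
  expect_equal(tortuosity_index(arc, "lowest_renal", "aortic_bifurcation"),
               pi / 2, tolerance = 1e-3)
})

test_that("helical tortuosity matches the closed-form arclength ratio", {
  r <- 20; pitch <- 8  # z advance per radian
  t <- seq(0, 3, length.out = 2000)
  helix <- centerline(cbind(r * cos(t), r * sin(t), pitch * t),
                      stations = c(lowest_renal = 1,
                                   aortic_bifurcation = 2000))
  arc_true <- 3 * sqrt(r^2 + pitch^2)
  chord_true <- sqrt((r * cos(3) - r)^2 + (r * sin(3))^2 + (pitch * 3)^2)
  expect_equal(tortuosity_index(helix, "lowest_renal",
                                "aortic_bifurcation"),
               arc_true / chord_true, tolerance = 1e-3)
})

test_that("tortuosity and angles are invariant under rigid motion and scaling", {
  set.seed(5)
  spec <- cohort_spec(n_patients = 1, seed = 3)
  m <- suppressWarnings(simulate_patient(spec, 1))$model_ct1
  cl <- m$centerline
  tor <- tortuosity_index(cl, "lowest_renal", "aortic_bifurcation")
  ang <- neck_angles(cl)
  R <- random_rotation_oracle(); t0 <- runif(3, -30, 30)
  moved <- centerline(sweep(cl$points %*% t(R), 2, t0, `+`), cl$stations)
  expect_equal(tortuosity_index(moved, "lowest_renal",
                                "aortic_bifurcation"), tor,
               tolerance = 1e-9)
  expect_equal(neck_angles(moved)$alpha_deg, ang$alpha_deg,
               tolerance = 1e-6)
  doubled <- centerline(2 * cl$points, cl$stations)
  expect_equal(tortuosity_index(doubled, "lowest_renal",
                                "aortic_bifurcation"), tor,
               tolerance = 1e-9)
  expect_equal(neck_angles(doubled, window_mm = 30)$beta_deg, ang$beta_deg,
               tolerance = 1e-6)
})

test_that("zero straight-line distance between stations is an explicit error", {
  th <- seq(0, 2 * pi, length.out = 100)
  loop <- cbind(10 * cos(th), 10 * sin(th), 0)
  loop[100, ] <- loop[1, ]  # closed loop: raceline length exactly zero
  cl <- centerline(loop, stations = c(lowest_renal = 1,
                                      aortic_bifurcation = 100))
  expect_error(tortuosity_index(cl, "lowest_renal", "aortic_bifurcation"),
               "straight-line")
})

bent_centerline <- function(alpha_deg, beta_deg) {
  # straight suprarenal along -z to s=20, neck to s=50, sac onward;
  # bends exactly at the stations, so window-averaged tangents lie
  # wholly within straight parts and angles are exact
  rot_x <- function(deg) {
    th <- deg * pi / 180
    matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
           3, 3, byrow = TRUE)
  }
  d0 <- c(0, 0, -1)
  d1 <- as.numeric(rot_x(alpha_deg) %*% d0)
  d2 <- as.numeric(rot_x(alpha_deg + beta_deg) %*% d0)
  pts <- matrix(0, 81, 3)
  for (i in 2:81) {
    d <- if (i <= 21) d0 else if (i <= 51) d1 else d2
    pts[i, ] <- pts[i - 1, ] + d
  }
  centerline(pts, stations = c(lowest_renal = 21, neck_end = 51,
                               aaa_start = 51))
}

test_that("neck angles recover planted bends, including 0 and 90 degrees", {
  straight <- bent_centerline(0, 0)
  a0 <- neck_angles(straight)
  expect_equal(a0$alpha_deg, 0, tolerance = 1e-9)
  expect_equal(a0$beta_deg, 0, tolerance = 1e-9)
  bent <- bent_centerline(30, 0)
  expect_equal(neck_angles(bent)$alpha_deg, 30, tolerance = 1e-6)
  sharp <- bent_centerline(0, 90)
  expect_equal(neck_angles(sharp)$beta_deg, 90, tolerance = 1e-6)
  both <- bent_centerline(17.5, 42)
  expect_equal(neck_angles(both)$alpha_deg, 17.5, tolerance = 1e-6)
  expect_equal(neck_angles(both)$beta_deg, 42, tolerance = 1e-6)
})

test_that("neck angle computation demands a resolvable suprarenal segment", {
  pts <- cbind(0, 0, seq(0, -60, length.out = 61))
  cl <- centerline(pts, stations = c(lowest_renal = 1, neck_end = 31,
                                     aaa_start = 31))
  expect_error(neck_angles(cl), "window")
})

test_that("max diameter and ILT thickness find planted maxima with proximal tie-breaking", {
  m <- straight_tube(lumen = 12.5, outer = 12.5)
  d <- suppressMessages(max_diameter(m))
  expect_equal(d$diameter_mm, 25)
  expect_equal(d$station, 1L)  # constant profile: proximal tie
  expect_message(max_diameter(m), "tied")

  n <- 101
  z <- seq(0, 100, length.out = n)
  outer <- 10 + 17.5 * exp(-(z - 60)^2 / 100)  # peak outer radius 27.5
  mg <- vessel_model(centerline(cbind(0, 0, z)), rep(10, n), outer)
  dg <- max_diameter(mg)
  expect_equal(dg$diameter_mm, 55, tolerance = 1e-9)
  expect_equal(dg$station, which.max(outer))

  expect_equal(max_ilt_thickness(straight_tube())$thickness_mm, 0)
  ilt_prof <- 7.7 * exp(-(z - 40)^2 / 64)
  mi <- vessel_model(centerline(cbind(0, 0, z)), 10 - ilt_prof, rep(10, n))
  ti <- max_ilt_thickness(mi)
  expect_equal(ti$thickness_mm, 7.7, tolerance = 1e-9)
  expect_equal(ti$station, which.max(ilt_prof))
  # two equal maxima -> proximal wins with a message
  lum <- rep(10, n); lum[c(30, 70)] <- 6
  m2 <- vessel_model(centerline(cbind(0, 0, z)), lum, rep(10, n))
  expect_message(t2 <- max_ilt_thickness(m2), "tied")
  expect_equal(t2$station, 30L)
})

test_that("outer diameter dominates lumen diameter whenever thrombus is present", {
  set.seed(9)
  spec <- cohort_spec(n_patients = 1, seed = 12)
  m <- suppressWarnings(simulate_patient(spec, 1))$model_ct1
  expect_true(all(m$outer_radius >= m$lumen_radius))
  expect_gte(max_diameter(m, "outer")$diameter_mm,
             max_diameter(m, "lumen")$diameter_mm)
})

test_that("cylinder volume matches the closed form and additivity is exact", {
  m <- straight_tube(n = 101, length_mm = 100, lumen = 10, outer = 10)
  v <- vessel_volumes(m)
  expect_equal(v$lumen_mm3, pi * 100 * 100, tolerance = 1e-3)
  expect_identical(v$ilt_mm3, v$vessel_mm3 - v$lumen_mm3)
  expect_equal(v$ilt_mm3, 0)

  set.seed(15)
  spec <- cohort_spec(n_patients = 1, seed = 8)
  ms <- suppressWarnings(simulate_patient(spec, 1))$model_ct1
  vs <- vessel_volumes(ms)
  expect_identical(vs$vessel_mm3, vs$lumen_mm3 + vs$ilt_mm3)
})

test_that("fusiform volume matches a fine-grid quadrature oracle within 0.1%", {
  rfun <- function(s) 10 + 8 * exp(-(s - 50)^2 / 200)
  s <- seq(0, 100, by = 1)
  m <- vessel_model(centerline(cbind(0, 0, s)), rfun(s), rfun(s))
  v <- vessel_volumes(m)$lumen_mm3
  oracle <- integrate(function(s) pi * rfun(s)^2, 0, 100,
                      rel.tol = 1e-10)$value
  expect_equal(v, oracle, tolerance = 1e-3)
})

test_that("doubling the sampling changes tortuosity and volume by under 0.1%", {
  rfun <- function(s) 10 + 8 * exp(-(s - 50)^2 / 200)
  mk <- function(ds) {
    s <- seq(0, 100, by = ds)
    pts <- cbind(5 * sin(pi * s / 100), 0, s)
    vessel_model(centerline(pts, stations = c(lowest_renal = 1,
                                              aortic_bifurcation =
                                                length(s))),
                 rfun(s), rfun(s))
  }
  m1 <- mk(1); m2 <- mk(0.5)
  t1 <- tortuosity_index(m1$centerline, "lowest_renal",
                         "aortic_bifurcation")
  t2 <- tortuosity_index(m2$centerline, "lowest_renal",
                         "aortic_bifurcation")
  expect_lt(abs(t1 - t2) / t2, 1e-3)
  v1 <- vessel_volumes(m1)$vessel_mm3; v2 <- vessel_volumes(m2)$vessel_mm3
  expect_lt(abs(v1 - v2) / v2, 1e-3)
})

test_that("neck measures return planted arclength and diameter, incl. juxtarenal limit", {
  st <- c(lowest_renal = 11, neck_end = 31, aaa_start = 31)
  s <- seq(0, 100, length.out = 101)
  m <- vessel_model(centerline(cbind(0, 0, s), stations = st),
                    rep(10, 101), rep(12, 101))
  nm <- neck_measures(m)
  expect_equal(nm$neck_length_mm, 20)
  expect_equal(nm$neck_diameter_mm, 24)
  st2 <- c(lowest_renal = 11, neck_end = 11, aaa_start = 11)
  m2 <- vessel_model(centerline(cbind(0, 0, s), stations = st2),
                     rep(10, 101), rep(12, 101))
  expect_equal(neck_measures(m2)$neck_length_mm, 0)
  st3 <- c(lowest_renal = 31, neck_end = 31, aaa_start = 11)
  m3 <- vessel_model(centerline(cbind(0, 0, s), stations = st3),
                     rep(10, 101), rep(12, 101))
  expect_error(neck_measures(m3), "precedes")
})

test_that("centerline construction enforces ordering and distinctness", {
  expect_error(centerline(matrix(1:3, 1, 3)), "at least 2")
  pts <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1))
  expect_error(centerline(pts), "distinct")
  pts2 <- cbind(0, 0, 0:10)
  expect_error(centerline(pts2, stations = c(lowest_renal = 8,
                                             aortic_bifurcation = 2)),
               "anatomical order")
  expect_error(vessel_model(centerline(pts2), rep(5, 11), rep(4, 11)),
               "outer radius below")
})
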