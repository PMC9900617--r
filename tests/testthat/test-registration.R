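make_corr <- function(src, tgt, labels = paste0("fix_", seq_len(nrow(src))),
                      val_src = NULL, val_tgt = NULL,
                      max_src = NULL, max_tgt = NULL, max_labels = NULL) {
  correspondence_set("pt", src, tgt, labels,
                     validation_source = val_src, validation_target = val_tgt,
                     maxpoint_source = max_src, maxpoint_target = max_tgt,
                     maxpoint_labels = max_labels)
}

test_that("identity and pure-translation correspondences are recovered exactly", {
  set.seed(1)
  src <- matrix(runif(27, -80, 80), 9, 3)
  tr <- estimate_transform(make_corr(src, src), "affine")
  expect_equal(tr$matrix, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tr$fit_rms, 0, tolerance = 1e-10)

  shift <- sweep(src, 2, c(10, 0, 0), `+`)
  tr2 <- estimate_transform(make_corr(src, shift), "rigid")
  expect_equal(tr2$matrix, diag(3), tolerance = 1e-8)
  expect_equal(tr2$translation, c(10, 0, 0), tolerance = 1e-8)
  expect_equal(tr2$fit_rms, 0, tolerance = 1e-10)
})

test_that("planted transforms of every mode are recovered entrywise", {
  set.seed(7)
  for (mode in c("rigid", "similarity", "affine")) {
    for (rep in 1:20) {
      sim <- simulate_correspondences(9, mode, noise_sd = 0,
                                      motions_mm = c(0, 0, 0))
      est <- estimate_transform(sim$corr, mode)
      expect_lt(max(abs(est$matrix - sim$transform$matrix)), 1e-8)
      expect_lt(max(abs(est$translation - sim$transform$translation)), 1e-8)
      expect_lt(est$fit_rms, 1e-8)
    }
  }
})

test_that("affine estimate agrees with an lm() normal-equations oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    src <- matrix(runif(3 * n, -80, 80), n, 3)
    tgt <- matrix(runif(3 * n, -80, 80), n, 3)  # arbitrary, noisy targets
    est <- estimate_transform(make_corr(src, tgt), "affine")
    ora <- lm_affine_oracle(src, tgt)
    expect_lt(max(abs(est$matrix - ora$A)), 1e-8)
    expect_lt(max(abs(est$translation - ora$t)), 1e-8)
  }
})

test_that("rigid estimate matches an independent Procrustes (vegan) solve", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (rep in 1:10) {
    src <- matrix(runif(27, -80, 80), 9, 3)
    tgt <- matrix(runif(27, -80, 80), 9, 3)
    est <- estimate_transform(make_corr(src, tgt), "rigid")
    pr <- vegan::procrustes(tgt, src, scale = FALSE, symmetric = FALSE)
    R_vegan <- t(pr$rotation)
    if (det(R_vegan) > 0) {  # vegan does not forbid reflections
      expect_lt(max(abs(est$matrix - R_vegan)), 1e-6)
      expect_lt(max(abs(est$translation - as.numeric(pr$translation))), 1e-6)
    }
    # scaled Procrustes cross-check for the similarity mode
    prs <- vegan::procrustes(tgt, src, scale = TRUE, symmetric = FALSE)
    ests <- estimate_transform(make_corr(src, tgt), "similarity")
    if (det(prs$rotation) > 0) {
      expect_lt(max(abs(ests$matrix - prs$scale * t(prs$rotation))), 1e-6)
    }
  }
})

test_that("rigid recovery of a planted rotation is orthogonal and exact", {
  set.seed(17)
  for (rep in 1:10) {
    R <- random_rotation_oracle()
    t0 <- runif(3, -50, 50)
    src <- matrix(runif(27, -80, 80), 9, 3)
    tgt <- sweep(src %*% t(R), 2, t0, `+`)
    est <- estimate_transform(make_corr(src, tgt), "affine")
    expect_lt(max(abs(crossprod(est$matrix) - diag(3))), 1e-8)
    expect_lt(max(abs(est$matrix - R)), 1e-8)
  }
})

test_that("fit RMS is monotone over the nested mode families", {
  set.seed(19)
  for (rep in 1:10) {
    sim <- simulate_correspondences(9, "affine", noise_sd = 3)
    rms <- sapply(c("affine", "similarity", "rigid"), function(m)
      estimate_transform(sim$corr, m)$fit_rms)
    expect_lte(rms[["affine"]], rms[["similarity"]] + 1e-10)
    expect_lte(rms[["similarity"]], rms[["rigid"]] + 1e-10)
  }
})

test_that("fit RMS, validation and motion distances are invariant under a common rigid motion", {
  set.seed(23)
  sim <- simulate_correspondences(9, "affine", noise_sd = 2,
                                  motions_mm = c(3, 8, 12))
  corr <- sim$corr
  est <- estimate_transform(corr, "affine")
  val <- validate_transform(est, corr)
  mot <- maxpoint_motion(est, corr, override = TRUE)
  R <- random_rotation_oracle(); t0 <- runif(3, -40, 40)
  mv <- function(P) {
    if (is.null(dim(P))) as.numeric(R %*% P + t0) else
      sweep(P %*% t(R), 2, t0, `+`)
  }
  corr2 <- correspondence_set("pt", mv(corr$fit_source), mv(corr$fit_target),
                              corr$fit_labels,
                              mv(corr$validation_source),
                              mv(corr$validation_target), "validation",
                              mv(corr$maxpoint_source),
                              mv(corr$maxpoint_target),
                              corr$maxpoint_labels)
  est2 <- estimate_transform(corr2, "affine")
  expect_equal(est2$fit_rms, est$fit_rms, tolerance = 1e-8)
  expect_equal(validate_transform(est2, corr2)$distance, val$distance,
               tolerance = 1e-8)
  expect_equal(maxpoint_motion(est2, corr2, override = TRUE)$distance_mm,
               mot$distance_mm, tolerance = 1e-8)
})

test_that("swapping timepoint roles with the inverse transform reproduces motions (noise-free affine)", {
  set.seed(29)
  sim <- simulate_correspondences(9, "affine", noise_sd = 0,
                                  motions_mm = c(2, 6, 11))
  corr <- sim$corr
  fwd <- estimate_transform(corr, "affine")
  m_fwd <- maxpoint_motion(fwd, corr)
  swapped <- correspondence_set("pt", corr$fit_target, corr$fit_source,
                                corr$fit_labels,
                                corr$validation_target,
                                corr$validation_source, "validation",
                                corr$maxpoint_target, corr$maxpoint_source,
                                corr$maxpoint_labels)
  bwd <- estimate_transform(swapped, "affine")
  expect_lt(max(abs(bwd$matrix - invert_transform(fwd)$matrix)), 1e-8)
  # distances measured in CT1 after mapping back differ from the CT2
  # distances only through the linear distortion; map CT2 residuals back
  m_bwd <- maxpoint_motion(bwd, swapped)
  pred_ct1 <- apply_transform(invert_transform(fwd),
                              apply_transform(fwd, corr$maxpoint_source))
  expect_equal(pred_ct1, corr$maxpoint_source, tolerance = 1e-6)
  expect_equal(nrow(m_bwd), nrow(m_fwd))
})

test_that("degenerate and undersized fit configurations raise explicit errors", {
  set.seed(31)
  # coplanar: z = 0 for all points -> affine degenerate, rigid fine
  src <- cbind(runif(6, -50, 50), runif(6, -50, 50), 0)
  tgt <- src
  expect_error(estimate_transform(make_corr(src, tgt), "affine"),
               "coplanar")
  expect_s3_class(estimate_transform(make_corr(src, tgt), "rigid"),
                  "linear_transform")
  # collinear: along one axis -> rigid degenerate too
  src2 <- cbind(seq(0, 50, length.out = 5), 0, 0)
  expect_error(estimate_transform(make_corr(src2, src2), "rigid"),
               "collinear")
  # too few pairs for affine
  src3 <- matrix(runif(9, -50, 50), 3, 3)
  expect_error(estimate_transform(make_corr(src3, src3), "affine"),
               "at least 4")
  # constructor bounds
  expect_error(make_corr(matrix(runif(6), 2, 3), matrix(runif(6), 2, 3)),
               "between 3 and 9")
  expect_error(make_corr(matrix(runif(30), 10, 3), matrix(runif(30), 10, 3)),
               "between 3 and 9")
})

test_that("the error for degenerate geometry names the offending landmarks", {
  src <- cbind(runif(5, -50, 50), runif(5, -50, 50), 0)
  err <- tryCatch(
    estimate_transform(make_corr(src, src,
                                 labels = c("sma", "left_renal",
                                            "right_renal", "lumbar_1",
                                            "aortic_bifurcation")),
                       "affine"),
    error = conditionMessage)
  expect_match(err, "left_renal")
  expect_match(err, "aortic_bifurcation")
})

test_that("validation gate uses a strict 15 mm inequality", {
  set.seed(37)
  src <- matrix(runif(27, -80, 80), 9, 3)
  # exact identity (estimated transforms carry ~1e-15 jitter that would
  # blur the boundary either way)
  id <- linear_transform(diag(3), c(0, 0, 0), "rigid", fit_rms = 0)
  # noise-free planted case: distance 0, accepted
  v0 <- validate_transform(id, make_corr(src, src,
                                         val_src = c(0, 0, 0),
                                         val_tgt = c(0, 0, 0)))
  expect_equal(v0$distance, 0)
  expect_true(v0$accepted)
  # boundary: exactly 15.0 mm must be rejected
  v15 <- validate_transform(id, make_corr(src, src,
                                          val_src = c(0, 0, 0),
                                          val_tgt = c(15, 0, 0)))
  expect_equal(v15$distance, 15)
  expect_false(v15$accepted)
  expect_true(validate_transform(id,
    make_corr(src, src, val_src = c(0, 0, 0), val_tgt = c(14.999, 0, 0))
  )$accepted)
  # missing validation pair is an explicit error
  expect_error(validate_transform(id, make_corr(src, src)), "validation")
})

test_that("maxpoint motion measures planted displacements in CT2 space", {
  set.seed(41)
  sim <- simulate_correspondences(9, "affine", noise_sd = 0,
                                  motions_mm = c(0, 5, 15))
  est <- estimate_transform(sim$corr, "affine")
  mot <- maxpoint_motion(est, sim$corr)
  expect_equal(mot$distance_mm, c(0, 5, 15), tolerance = 1e-6)
  expect_equal(mot$label, c("max_ilt", "max_pws", "max_pwri"))
})

test_that("motion on a gate-rejected transform errors unless overridden", {
  set.seed(43)
  src <- matrix(runif(27, -80, 80), 9, 3)
  corr <- make_corr(src, src, val_src = c(0, 0, 0), val_tgt = c(40, 0, 0),
                    max_src = matrix(c(1, 2, 3), 1, 3),
                    max_tgt = matrix(c(1, 2, 3), 1, 3),
                    max_labels = "max_ilt")
  id <- estimate_transform(corr, "affine")
  expect_error(maxpoint_motion(id, corr), "override")
  expect_message(m <- maxpoint_motion(id, corr, override = TRUE),
                 "override")
  expect_equal(m$distance_mm, 0)
})

test_that("the validation label may not appear among the fit labels", {
  src <- matrix(runif(27, -80, 80), 9, 3)
  expect_error(
    correspondence_set("pt", src, src, paste0("fix_", 1:9),
                       validation_source = c(0, 0, 0),
                       validation_target = c(0, 0, 0),
                       validation_label = "fix_3"),
    "held out")
})

test_that("apply_transform matches direct arithmetic and invert composes to identity", {
  set.seed(47)
  A <- matrix(runif(9, -1, 1), 3, 3) + diag(3)
  t0 <- runif(3, -20, 20)
  tr <- linear_transform(A, t0, "affine")
  p <- c(3.5, -2, 11)
  expect_equal(apply_transform(tr, p), as.numeric(A %*% p + t0),
               tolerance = 1e-12)
  expect_equal(apply_transform(linear_transform(diag(3), c(0, 0, 5),
                                                "rigid"), c(0, 0, 0)),
               c(0, 0, 5))
  back <- apply_transform(invert_transform(tr), apply_transform(tr, p))
  expect_equal(back, p, tolerance = 1e-9)
})
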