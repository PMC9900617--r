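#' Construct a linear transform object
#'
#' A linear transform maps CT1 coordinates into CT2 space as
#' `matrix %*% p + translation`. Mode `"rigid"` constrains the matrix to
#' a proper rotation, `"similarity"` to a positive scalar times a proper
#' rotation, `"affine"` is the full 12-parameter family.
#'
#' @param matrix 3 x 3 numeric matrix.
#' @param translation length-3 numeric vector, mm.
#' @param mode `"rigid"`, `"similarity"` or `"affine"`.
#' @param fit_rms root-mean-square residual over the fit pairs, mm.
#' @return Object of class `linear_transform`.
#' @export
linear_transform <- function(matrix, translation, mode, fit_rms = NA_real_) {
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(matrix)),
            all(is.finite(translation)))
  mode <- match.arg(mode, c("rigid", "similarity", "affine"))
  tol <- 1e-8
  if (mode %in% c("rigid", "similarity")) {
    s <- if (mode == "rigid") 1 else (det(matrix))^(1 / 3)
    if (mode == "similarity" && !(s > 0)) {
      stop("similarity transform requires positive scale", call. = FALSE)
    }
    R <- matrix / s
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
      stop(mode, " transform matrix is not (scaled) proper-orthogonal ",
           "within tolerance", call. = FALSE)
    }
  }
  if (!is.na(fit_rms) && fit_rms < -tol) stop("fit_rms must be >= 0")
  structure(list(matrix = matrix, translation = translation,
                 mode = mode, fit_rms = fit_rms),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat("<linear_transform> mode:", x$mode,
      " fit RMS:", format(x$fit_rms, digits = 4), "mm\n")
  cat("matrix:\n"); print(round(x$matrix, 6))
  cat("translation (mm):", round(x$translation, 4), "\n")
  invisible(x)
}

centered_condition <- function(Xc, mode) {
  d <- svd(Xc, nu = 0L, nv = 0L)$d
  # rigid/similarity are well-posed from a plane (3 non-collinear points);
  # affine additionally needs rank 3 (non-coplanar).
  denom <- if (mode == "affine") d[3L] else d[2L]
  if (denom <= .Machine$double.eps * d[1L]) Inf else d[1L] / denom
}

#' Estimate the least-squares transform between paired landmarks
#'
#' Fits, over the fit pairs only, the transform of the requested family
#' minimising the sum of squared residuals between transformed CT1
#' points and CT2 points: full affine by normal equations on centered
#' coordinates, rigid by orthogonal Procrustes (SVD with reflection
#' guard), similarity by scaled Procrustes.
#'
#' @param corr a [correspondence_set()].
#' @param mode transform family; `"affine"` (default), `"similarity"` or
#'   `"rigid"`. Affine is the default because aneurysm growth implies
#'   non-rigid landmark motion.
#' @param cond_bound maximum allowed condition number of the centered
#'   source design matrix; beyond it the configuration is declared
#'   degenerate (coplanar/collinear) rather than silently ill-posed.
#' @return A [linear_transform()] with `fit_rms` filled in.
#' @export
estimate_transform <- function(corr,
                               mode = c("affine", "similarity", "rigid"),
                               cond_bound = 1e6) {
  stopifnot(inherits(corr, "correspondence_set"))
  mode <- match.arg(mode)
  X <- corr$fit_source
  Y <- corr$fit_target
  n <- nrow(X)
  n_min <- if (mode == "affine") 4L else 3L
  if (n < n_min) {
    stop("mode '", mode, "' needs at least ", n_min,
         " fit pairs, got ", n, call. = FALSE)
  }
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2L, xbar); Yc <- sweep(Y, 2L, ybar)
  kappa <- centered_condition(Xc, mode)
  if (!is.finite(kappa) || kappa > cond_bound) {
    stop("degenerate fit-point geometry (",
         if (mode == "affine") "coplanar" else "collinear",
         " beyond condition bound ", format(cond_bound),
         ") for landmarks: ", paste(corr$fit_labels, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "affine") {
    At <- solve(crossprod(Xc), crossprod(Xc, Yc))
    A <- t(At)
  } else {
    H <- crossprod(Xc, Yc)                       # sum_i x_i y_i^T
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))             # reflection guard
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    if (mode == "similarity") {
      s <- sum(sv$d * c(1, 1, d)) / sum(Xc^2)
      if (!(s > 0)) stop("non-positive similarity scale", call. = FALSE)
      A <- s * R
    } else {
      A <- R
    }
  }
  tr <- ybar - as.numeric(A %*% xbar)
  pred <- transform_points(A, tr, X)
  rms <- sqrt(mean(rowSums((pred - Y)^2)))
  linear_transform(A, tr, mode, fit_rms = rms)
}

transform_points <- function(A, tr, P) {
  sweep(P %*% t(A), 2L, tr, `+`)
}

#' Apply a linear transform to points
#'
#' @param transform a [linear_transform()].
#' @param p length-3 vector or n x 3 matrix of points, mm.
#' @return Same shape as `p`.
#' @export
apply_transform <- function(transform, p) {
  stopifnot(inherits(transform, "linear_transform"))
  if (is.null(dim(p))) {
    as.numeric(transform$matrix %*% as.numeric(p) + transform$translation)
  } else {
    transform_points(transform$matrix, transform$translation, as_xyz_matrix(p))
  }
}

#' Invert a linear transform
#'
#' @param transform a [linear_transform()].
#' @return The inverse [linear_transform()] (same mode, `fit_rms` NA).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "linear_transform"))
  Ai <- solve(transform$matrix)
  linear_transform(Ai, -as.numeric(Ai %*% transform$translation),
                   transform$mode)
}

#' Validate a transform against the held-out validation point
#'
#' The transform is accepted when the Euclidean distance between the
#' predicted and the actual CT2 position of the validation landmark is
#' strictly below the threshold (default 15 mm).
#'
#' @param transform a [linear_transform()].
#' @param corr a [correspondence_set()] carrying a validation pair.
#' @param threshold acceptance gate, mm; strict `<`.
#' @return List of class `validation_result`: `label`, `distance` (mm),
#'   `threshold`, `accepted`.
#' @export
validate_transform <- function(transform, corr, threshold = 15) {
  stopifnot(inherits(transform, "linear_transform"),
            inherits(corr, "correspondence_set"), threshold > 0)
  if (is.null(corr$validation_source)) {
    stop("correspondence set has no validation pair; the gate cannot be ",
         "evaluated", call. = FALSE)
  }
  pred <- apply_transform(transform, corr$validation_source)
  dist <- sqrt(sum((pred - corr$validation_target)^2))
  structure(list(label = corr$validation_label,
                 predicted_position = pred,
                 distance = dist, threshold = threshold,
                 accepted = dist < threshold),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", x$label, ":",
      format(x$distance, digits = 4), "mm",
      if (x$accepted) "< " else ">=", x$threshold, "mm ->",
      if (x$accepted) "accepted" else "rejected", "\n")
  invisible(x)
}

#' Spatial motion of the maximum points
#'
#' Projects each maximum point (max ILT thickness, peak wall stress,
#' peak wall rupture index) from CT1 into CT2 space with the estimated
#' transform and measures the Euclidean distance, in CT2 coordinates, to
#' the position where the maximum actually appeared in CT2. The motion
#' is only computed when the validation gate accepted the transform,
#' unless `override = TRUE` (a message records the override).
#'
#' @param transform a [linear_transform()].
#' @param corr a [correspondence_set()] with at least one maxpoint pair.
#' @param threshold validation gate threshold, mm.
#' @param override compute motions even for a rejected transform.
#' @return data.frame with one row per maximum point: `label`,
#'   predicted and actual CT2 coordinates, `distance_mm`.
#' @export
maxpoint_motion <- function(transform, corr, threshold = 15,
                            override = FALSE) {
  stopifnot(inherits(transform, "linear_transform"),
            inherits(corr, "correspondence_set"))
  if (is.null(corr$maxpoint_source) || nrow(corr$maxpoint_source) == 0L) {
    stop("correspondence set has no maximum-point pairs", call. = FALSE)
  }
  val <- validate_transform(transform, corr, threshold)
  if (!val$accepted) {
    if (!override) {
      stop("validation gate rejected the transform (",
           format(val$distance, digits = 4), " mm >= ", threshold,
           " mm); pass override = TRUE to compute motions anyway",
           call. = FALSE)
    }
    message("maxpoint_motion: gate rejected (",
            format(val$distance, digits = 4),
            " mm) but override requested; motions computed anyway")
  }
  pred <- apply_transform(transform, corr$maxpoint_source)
  act <- corr$maxpoint_target
  d <- sqrt(rowSums((pred - act)^2))
  data.frame(label = corr$maxpoint_labels,
             pred_x_mm = pred[, 1L], pred_y_mm = pred[, 2L],
             pred_z_mm = pred[, 3L],
             actual_x_mm = act[, 1L], actual_y_mm = act[, 2L],
             actual_z_mm = act[, 3L],
             distance_mm = d,
             row.names = NULL)
}

#' Assemble a transform report
#'
#' Bundles the estimated transform, validation result and maximum-point
#' motions of one patient into a list ready for JSON serialisation
#' (matrix row-major).
#'
#' @param transform a [linear_transform()].
#' @param validation a result from [validate_transform()].
#' @param motion optional data.frame from [maxpoint_motion()].
#' @param patient_id optional identifier.
#' @return A plain list.
#' @export
transform_report <- function(transform, validation, motion = NULL,
                             patient_id = NULL) {
  rep <- list(
    patient_id = patient_id,
    mode = transform$mode,
    matrix_row_major = as.numeric(t(transform$matrix)),
    translation_mm = transform$translation,
    fit_rms_mm = transform$fit_rms,
    validation = list(label = validation$label,
                      distance_mm = validation$distance,
                      threshold_mm = validation$threshold,
                      accepted = validation$accepted)
  )
  if (!is.null(motion)) {
    rep$motion <- setNames(as.list(motion$distance_mm), motion$label)
  }
  rep
}

#' Write a transform report to JSON
#'
#' @param report list from [transform_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
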