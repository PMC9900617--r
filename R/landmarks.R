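#' Labeled 3-D landmark set for one patient-timepoint
#'
#' A landmark set holds the anatomical points digitised on one CT study:
#' fit points (renal arteries, SMA, aortic bifurcation, common iliac
#' origins, lumbar arteries) used to estimate the inter-timepoint
#' transformation, one validation point held out of the fit, and up to
#' three maximum points (max ILT thickness, max wall stress, max rupture
#' index) whose motion is measured.
#'
#' Coordinates are world/scanner millimetres in a right-handed frame.
#' The axis-orientation convention (LPS, RAS, ...) is irrelevant to the
#' method provided both timepoints of a patient use the same one; the
#' package never converts between conventions.
#'
#' @param patient_id character scalar.
#' @param timepoint `"ct1"` or `"ct2"`.
#' @param landmarks data.frame with columns `label`, `role`
#'   (`"fit"`, `"validation"` or `"maxpoint"`), `x_mm`, `y_mm`, `z_mm`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(patient_id, timepoint = c("ct1", "ct2"), landmarks) {
  timepoint <- match.arg(timepoint)
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  req <- c("label", "role", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(req, names(landmarks))
  if (length(missing_cols)) {
    stop("landmark table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  landmarks <- as.data.frame(landmarks)[req]
  bad_role <- setdiff(unique(landmarks$role), c("fit", "validation", "maxpoint"))
  if (length(bad_role)) {
    stop("unknown landmark role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(xyz))) {
    bad <- landmarks$label[!apply(is.finite(xyz), 1L, all)]
    stop("non-finite coordinates for landmark(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- landmarks$label[duplicated(landmarks$label)]
  if (length(dup)) {
    stop("duplicate landmark label(s) within one set: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, timepoint = timepoint,
         landmarks = landmarks),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> patient", x$patient_id, "timepoint", x$timepoint, "\n")
  cat("  ", sum(x$landmarks$role == "fit"), "fit,",
      sum(x$landmarks$role == "validation"), "validation,",
      sum(x$landmarks$role == "maxpoint"), "maxpoint landmarks\n")
  invisible(x)
}

lm_points <- function(set, role) {
  sub <- set$landmarks[set$landmarks$role == role, , drop = FALSE]
  m <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- sub$label
  m
}

#' Paired landmark correspondences between two timepoints
#'
#' @param patient_id character scalar.
#' @param fit_source,fit_target n x 3 matrices of matched fit points
#'   (CT1 and CT2 coordinates, mm); rows correspond.
#' @param fit_labels character vector of length n.
#' @param validation_source,validation_target length-3 validation point
#'   coordinates, or `NULL` if absent.
#' @param validation_label label of the validation point.
#' @param maxpoint_source,maxpoint_target k x 3 matrices (k <= 3) of
#'   maximum-point coordinates, or `NULL`.
#' @param maxpoint_labels character vector of length k.
#' @return An object of class `correspondence_set`.
#' @export
correspondence_set <- function(patient_id, fit_source, fit_target, fit_labels,
                               validation_source = NULL,
                               validation_target = NULL,
                               validation_label = "validation",
                               maxpoint_source = NULL,
                               maxpoint_target = NULL,
                               maxpoint_labels = NULL) {
  fit_source <- as_xyz_matrix(fit_source)
  fit_target <- as_xyz_matrix(fit_target)
  n <- nrow(fit_source)
  stopifnot(nrow(fit_target) == n, length(fit_labels) == n)
  if (n < 3L || n > 9L) {
    stop("need between 3 and 9 fit pairs, got ", n, call. = FALSE)
  }
  if (!is.null(validation_source)) {
    validation_source <- as.numeric(validation_source)
    validation_target <- as.numeric(validation_target)
    stopifnot(length(validation_source) == 3L,
              length(validation_target) == 3L)
    if (validation_label %in% fit_labels) {
      stop("validation label '", validation_label,
           "' also appears among fit labels; the validation point must be ",
           "held out of the fit", call. = FALSE)
    }
  }
  if (!is.null(maxpoint_source)) {
    maxpoint_source <- as_xyz_matrix(maxpoint_source)
    maxpoint_target <- as_xyz_matrix(maxpoint_target)
    stopifnot(nrow(maxpoint_source) == nrow(maxpoint_target),
              nrow(maxpoint_source) <= 3L,
              length(maxpoint_labels) == nrow(maxpoint_source))
  }
  structure(
    list(patient_id = patient_id,
         fit_source = fit_source, fit_target = fit_target,
         fit_labels = as.character(fit_labels),
         validation_source = validation_source,
         validation_target = validation_target,
         validation_label = validation_label,
         maxpoint_source = maxpoint_source,
         maxpoint_target = maxpoint_target,
         maxpoint_labels = maxpoint_labels),
    class = "correspondence_set"
  )
}

as_xyz_matrix <- function(x) {
  m <- if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L) else
    as.matrix(x)
  if (ncol(m) != 3L) stop("expected 3 columns (x, y, z)", call. = FALSE)
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  m
}

#' Build correspondences from two landmark sets of the same patient
#'
#' Matches landmarks by label between the two timepoints. Fit landmarks
#' present at only one timepoint are dropped with a warning; the
#' validation and maximum points must either be present at both
#' timepoints or absent.
#'
#' @param ct1,ct2 [landmark_set()] objects for the same patient.
#' @return A [correspondence_set()].
#' @export
build_correspondences <- function(ct1, ct2) {
  stopifnot(inherits(ct1, "landmark_set"), inherits(ct2, "landmark_set"))
  if (ct1$patient_id != ct2$patient_id) {
    stop("landmark sets belong to different patients: ",
         ct1$patient_id, " vs ", ct2$patient_id, call. = FALSE)
  }
  f1 <- lm_points(ct1, "fit"); f2 <- lm_points(ct2, "fit")
  common <- intersect(rownames(f1), rownames(f2))
  lost <- setdiff(union(rownames(f1), rownames(f2)), common)
  if (length(lost)) {
    warning("fit landmark(s) present at only one timepoint dropped: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  v1 <- lm_points(ct1, "validation"); v2 <- lm_points(ct2, "validation")
  vlab <- intersect(rownames(v1), rownames(v2))
  m1 <- lm_points(ct1, "maxpoint"); m2 <- lm_points(ct2, "maxpoint")
  mlab <- intersect(rownames(m1), rownames(m2))
  correspondence_set(
    patient_id = ct1$patient_id,
    fit_source = f1[common, , drop = FALSE],
    fit_target = f2[common, , drop = FALSE],
    fit_labels = common,
    validation_source = if (length(vlab)) v1[vlab[1L], ] else NULL,
    validation_target = if (length(vlab)) v2[vlab[1L], ] else NULL,
    validation_label = if (length(vlab)) vlab[1L] else "validation",
    maxpoint_source = if (length(mlab)) m1[mlab, , drop = FALSE] else NULL,
    maxpoint_target = if (length(mlab)) m2[mlab, , drop = FALSE] else NULL,
    maxpoint_labels = if (length(mlab)) mlab else NULL
  )
}
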