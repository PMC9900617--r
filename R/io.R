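#' Read landmark sets from CSV
#'
#' Expected columns: `patient_id`, `timepoint` (`ct1`/`ct2`), `label`,
#' `role` (`fit`/`validation`/`maxpoint`), `x_mm`, `y_mm`, `z_mm`; one
#' row per landmark; comma-separated, dot decimal, UTF-8, header row
#' mandatory. Schema violations are reported with the offending row
#' numbers (header = row 1).
#'
#' @param path CSV file.
#' @return Named list of [landmark_set()]s, names
#'   `<patient_id>.<timepoint>`.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("patient_id", "timepoint", "label", "role", "x_mm", "y_mm",
           "z_mm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("landmark CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rowno <- seq_len(nrow(df)) + 1L
  bad_tp <- !df$timepoint %in% c("ct1", "ct2")
  if (any(bad_tp)) {
    stop("invalid timepoint (must be ct1/ct2) at row(s): ",
         paste(rowno[bad_tp], collapse = ", "), call. = FALSE)
  }
  bad_role <- !df$role %in% c("fit", "validation", "maxpoint")
  if (any(bad_role)) {
    stop("invalid role at row(s): ", paste(rowno[bad_role], collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  bad_num <- !apply(is.finite(xyz), 1L, all)
  if (any(bad_num)) {
    stop("non-finite coordinates at row(s): ",
         paste(rowno[bad_num], collapse = ", "), call. = FALSE)
  }
  key <- paste(df$patient_id, df$timepoint, sep = ".")
  dup <- duplicated(data.frame(key, df$label))
  if (any(dup)) {
    stop("duplicate label within a patient-timepoint at row(s): ",
         paste(rowno[dup], collapse = ", "), call. = FALSE)
  }
  sets <- lapply(split(df, key), function(sub) {
    landmark_set(as.character(sub$patient_id[1L]), sub$timepoint[1L],
                 sub[, c("label", "role", "x_mm", "y_mm", "z_mm")])
  })
  for (nm in names(sets)) {
    lm <- sets[[nm]]$landmarks
    if (sum(lm$role == "fit") < 4L) {
      warning("patient-timepoint ", nm, " has fewer than 4 fit landmarks",
              call. = FALSE)
    }
    if (!any(lm$role == "validation")) {
      warning("patient-timepoint ", nm, " has no validation landmark",
              call. = FALSE)
    }
  }
  sets
}

#' Write landmark sets to CSV
#'
#' @param sets a [landmark_set()] or list of them.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    cbind(patient_id = s$patient_id, timepoint = s$timepoint, s$landmarks)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a vessel model to JSON
#'
#' Schema (version 1): `points` (n x 3 mm), `lumen_radius_mm`,
#' `outer_radius_mm` (length n), `stations` (name -> 1-based index).
#'
#' @param m a [vessel_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vessel_model <- function(m, path) {
  stopifnot(inherits(m, "vessel_model"))
  jsonlite::write_json(list(
    schema = "aaamotion/vessel_model/1",
    points = unname(m$centerline$points),
    lumen_radius_mm = m$lumen_radius,
    outer_radius_mm = m$outer_radius,
    stations = as.list(m$centerline$stations)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel model from JSON
#'
#' @param path file written by [write_vessel_model()].
#' @return A [vessel_model()].
#' @export
read_vessel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "aaamotion/vessel_model/1")) {
    stop("unrecognised vessel model schema: ", obj$schema, call. = FALSE)
  }
  cl <- centerline(obj$points, unlist(obj$stations))
  vessel_model(cl, obj$lumen_radius_mm, obj$outer_radius_mm)
}

#' Default pipeline configuration
#'
#' @param seed integer seed for the simulation stage.
#' @param n_patients simulated cohort size.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, n_patients = 32L) {
  list(
    seed = as.integer(seed),
    registration = list(mode = "affine", threshold_mm = 15,
                        cond_bound = 1e6),
    biomech = list(systolic_mmHg = 140, diastolic_mmHg = 80,
                   analysis = "map", wall_thickness_mm = 2,
                   ilt_attenuation_per_mm = 0.03, base_strength_kpa = 800,
                   ilt_strength_loss_kpa_per_mm = 15, floor_kpa = 300),
    simulation = list(n_patients = as.integer(n_patients),
                      landmark_noise_sd = 1.5,
                      rho_pws = 0.68, rho_pwri = 0.60),
    stats = list(alpha = 0.05, bh_adjust = FALSE),
    log_level = "info"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Fields missing from the file are filled from [default_config()];
#' the configuration round-trips losslessly through JSON.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else stop("unsupported config extension: .", ext, call. = FALSE)
  modifyList(default_config(), cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
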