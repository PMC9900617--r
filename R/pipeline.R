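#' Run the full analysis pipeline
#'
#' Stages: load or simulate patients -> per-timepoint geometric metrics
#' -> surrogate biomechanical metrics -> transform estimation +
#' validation gate -> maximum-point motion -> cohort tables. Patients
#' whose validation distance fails the strict 15 mm gate are excluded
#' from the motion analyses only (the gate is the inclusion rule for
#' the transformation step, not for geometric/biomechanical change) and
#' listed in the manifest. A stage error for one patient is logged and
#' the pipeline continues with the remaining patients.
#'
#' @param config nested list as from [default_config()]; when
#'   `config$simulation` is present the cohort is simulated, otherwise
#'   `config$paths$landmarks` (CSV) and `config$paths$models`
#'   (directory of `<patient>.<timepoint>.json` vessel models) are
#'   loaded.
#' @param cohort optionally, a pre-built [simulate_cohort()] result to
#'   analyse (overrides the simulation stage; useful for testing).
#' @return list of class `pipeline_result`: `tables`
#'   ([build_cohort_tables()] output), `records` (measured per-patient
#'   data.frame), `reports` (per-patient transform reports),
#'   `exclusions` (data.frame of gate failures), `errors`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  t0 <- Sys.time()
  warnings_log <- character()
  errors <- list()
  exclusions <- list()

  if (is.null(cohort) && !is.null(config$simulation)) {
    sim <- config$simulation
    spec <- cohort_spec(
      n_patients = sim$n_patients %||% 32L,
      seed = config$seed %||% 1L,
      landmark_noise_sd = sim$landmark_noise_sd %||% 1.5,
      rho_pws = sim$rho_pws %||% 0.68,
      rho_pwri = sim$rho_pwri %||% 0.60)
    cohort <- simulate_cohort(spec)
  }
  if (is.null(cohort)) {
    patients <- load_patients_from_paths(config$paths)
  } else {
    patients <- lapply(cohort$patients, function(p) {
      list(patient_id = p$patient_id, ct1 = p$ct1, ct2 = p$ct2,
           model_ct1 = p$model_ct1, model_ct2 = p$model_ct2,
           interval_months = p$interval_months)
    })
  }
  if (!length(patients)) {
    stop("pipeline received no patients", call. = FALSE)
  }

  reg <- config$registration
  bio <- config$biomech
  pres <- pressure_spec(bio$systolic_mmHg %||% 140,
                        bio$diastolic_mmHg %||% 80,
                        bio$analysis %||% "map")
  records <- list()
  reports <- list()
  for (p in patients) {
    res <- tryCatch({
      analyse_patient(p, reg, bio, pres)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[p$patient_id]] <- conditionMessage(res)
      next
    }
    if (!res$validation$accepted) {
      exclusions[[p$patient_id]] <- data.frame(
        patient_id = p$patient_id,
        validation_distance_mm = res$validation$distance,
        threshold_mm = res$validation$threshold)
    }
    records[[p$patient_id]] <- res$record
    reports[[p$patient_id]] <- res$report
  }
  if (!length(records)) {
    stop("no patient could be analysed; first error: ",
         if (length(errors)) errors[[1L]] else "unknown", call. = FALSE)
  }
  records <- rbind_fill(records)
  rownames(records) <- NULL

  tables <- tryCatch(
    build_cohort_tables(records, alpha = config$stats$alpha %||% 0.05,
                        bh_adjust = isTRUE(config$stats$bh_adjust)),
    error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste("cohort tables not built:",
                               conditionMessage(e)))
      NULL
    })

  manifest <- list(
    tool = "aaamotion",
    version = as.character(utils::packageVersion("aaamotion")),
    config_hash = config_hash(config),
    n_patients_in = length(patients),
    n_patients_analysed = nrow(records),
    n_gate_excluded = length(exclusions),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings_log,
    errors = errors)

  structure(list(tables = tables, records = records, reports = reports,
                 exclusions = if (length(exclusions))
                   do.call(rbind, exclusions) else NULL,
                 errors = errors, manifest = manifest),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data.frames whose columns may differ (gate-rejected patients
# have no motion columns); missing cells become NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  }))
}

load_patients_from_paths <- function(paths) {
  if (is.null(paths$landmarks)) {
    stop("config$paths$landmarks is required when no simulation is ",
         "configured", call. = FALSE)
  }
  sets <- read_landmarks(paths$landmarks)
  ids <- unique(sub("\\.(ct1|ct2)$", "", names(sets)))
  lapply(setNames(ids, ids), function(id) {
    ct1 <- sets[[paste0(id, ".ct1")]]
    ct2 <- sets[[paste0(id, ".ct2")]]
    if (is.null(ct1) || is.null(ct2)) {
      stop("patient ", id, " lacks one of the two timepoints",
           call. = FALSE)
    }
    m1 <- m2 <- NULL
    if (!is.null(paths$models)) {
      f1 <- file.path(paths$models, paste0(id, ".ct1.json"))
      f2 <- file.path(paths$models, paste0(id, ".ct2.json"))
      if (file.exists(f1)) m1 <- read_vessel_model(f1)
      if (file.exists(f2)) m2 <- read_vessel_model(f2)
    }
    list(patient_id = id, ct1 = ct1, ct2 = ct2,
         model_ct1 = m1, model_ct2 = m2, interval_months = NA_real_)
  })
}

analyse_patient <- function(p, reg, bio, pres) {
  corr <- build_correspondences(p$ct1, p$ct2)
  tr <- estimate_transform(corr, mode = reg$mode %||% "affine",
                           cond_bound = reg$cond_bound %||% 1e6)
  val <- validate_transform(tr, corr, threshold = reg$threshold_mm %||% 15)
  motion <- NULL
  if (val$accepted && !is.null(corr$maxpoint_source)) {
    motion <- maxpoint_motion(tr, corr, threshold = reg$threshold_mm %||% 15)
  }
  rec <- data.frame(patient_id = p$patient_id,
                    interval_months = p$interval_months,
                    fit_rms_mm = tr$fit_rms,
                    validation_distance_mm = val$distance,
                    gate_accepted = val$accepted)
  metrics_of <- function(m) {
    g <- geometric_metrics(m)
    sf <- stress_field(m, pres,
                       wall_thickness = bio$wall_thickness_mm %||% 2,
                       ilt_attenuation = bio$ilt_attenuation_per_mm %||% 0.03,
                       base_strength = bio$base_strength_kpa %||% 800,
                       ilt_strength_loss =
                         bio$ilt_strength_loss_kpa_per_mm %||% 15,
                       floor = bio$floor_kpa %||% 300)
    bm <- biomech_metrics(sf, m)
    cbind(g, data.frame(pws_kpa = bm$pws_kpa, pwri = bm$pwri,
                        mean_ilt_stress_kpa = bm$mean_ilt_stress_kpa))
  }
  if (!is.null(p$model_ct1) && !is.null(p$model_ct2)) {
    g1 <- metrics_of(p$model_ct1)
    g2 <- metrics_of(p$model_ct2)
    names(g1) <- paste0(names(g1), "_ct1")
    names(g2) <- paste0(names(g2), "_ct2")
    rec <- cbind(rec, g1, g2)
  }
  if (!is.null(motion)) {
    for (i in seq_len(nrow(motion))) {
      rec[[paste0("motion_", motion$label[i], "_mm")]] <-
        motion$distance_mm[i]
    }
  }
  list(record = rec, validation = val,
       report = transform_report(tr, val, motion, p$patient_id))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_patients_analysed, "of",
      x$manifest$n_patients_in, "patients analysed;",
      x$manifest$n_gate_excluded, "excluded by the validation gate\n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the cohort tables, the measured per-patient record table, the
#' per-patient transform reports and the run manifest. Tables contain
#' no timestamps, so repeated runs under the same seed and config are
#' byte-identical; the manifest (which carries the start time) is the
#' only non-reproducible file.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$tables)) write_cohort_tables(result$tables, dir)
  write.csv(result$records, file.path(dir, "patient_records.csv"),
            row.names = FALSE)
  if (!is.null(result$exclusions)) {
    write.csv(result$exclusions, file.path(dir, "gate_exclusions.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(result$reports,
                       file.path(dir, "transform_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
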