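#' Normalise a change to a per-12-months rate
#'
#' Applied per patient *before* any cohort summary, so cohort medians of
#' normalised changes are medians of per-patient rates (never the ratio
#' of medians).
#'
#' @param delta change between the two studies (any unit).
#' @param interval_months positive interval between the studies.
#' @return `delta * 12 / interval_months`.
#' @export
normalize_per_12_months <- function(delta, interval_months) {
  if (any(!is.na(interval_months) & interval_months <= 0)) {
    stop("interval_months must be positive", call. = FALSE)
  }
  delta * 12 / interval_months
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation (R's default type-7 convention);
#' the convention matters because IQRs differ across quantile types.
#' Missing values are excluded and counted.
#'
#' @param values numeric vector with at least one non-missing value.
#' @return list `median`, `q1`, `q3`, `n`, `n_missing`.
#' @export
median_iqr <- function(values) {
  n_missing <- sum(is.na(values))
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       n = length(values), n_missing = n_missing)
}

#' Paired Wilcoxon signed-rank test between the two timepoints
#'
#' Two-sided signed-rank test of CT2 versus CT1. Zero differences are
#' dropped (standard signed-rank convention) and counted; the p-value
#' is exact when the non-zero absolute differences are untied, exact by
#' direct sign-pattern enumeration when they are tied but few (n <= 15),
#' and a normal approximation with continuity and tie correction
#' otherwise. When every difference is zero the result is flagged
#' degenerate with p = 1.
#'
#' @param ct1,ct2 paired numeric vectors of equal length.
#' @return list `statistic` (V), `p_value`, `n_used`, `n_zero`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(ct1, ct2) {
  stopifnot(length(ct1) == length(ct2))
  keep <- complete.cases(ct1, ct2)
  d <- ct2[keep] - ct1[keep]
  n_zero <- sum(d == 0)
  d_nz <- d[d != 0]
  if (!length(d_nz)) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                n_zero = n_zero, degenerate = TRUE))
  }
  n <- length(d_nz)
  r <- rank(abs(d_nz))
  has_ties <- anyDuplicated(r) > 0L
  if (has_ties && n <= 15L) {
    # tied absolute differences defeat the signed-rank distribution, but
    # the exact two-sided p is still available by enumerating all 2^n
    # sign patterns (feasible for small n)
    v_obs <- sum(r[d_nz > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- if (v_obs > n * (n + 1) / 4) 2 * mean(v_all >= v_obs) else
      2 * mean(v_all <= v_obs)
    return(list(statistic = v_obs, p_value = min(1, p), n_used = n,
                n_zero = n_zero, degenerate = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(d_nz, exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = n, n_zero = n_zero, degenerate = FALSE)
}

#' Two-sample Mann-Whitney rank-sum test
#'
#' Two-sided; exact when both groups are small and untied, otherwise a
#' normal approximation with continuity and tie correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list `statistic` (W), `p_value`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = NULL,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(group_a), n_b = length(group_b))
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete observations; p from the t transform with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete
#'   pairs and positive variance in each.
#' @return list `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

record_variables <- function(records) {
  v <- grep("_ct1$", names(records), value = TRUE)
  sub("_ct1$", "", v)
}

fmt_miqr <- function(x) {
  m <- median_iqr(x)
  sprintf("%.4g [%.4g to %.4g]", m$median, m$q1, m$q3)
}

#' Cohort-level change, correlation and group-comparison tables
#'
#' Reproduces the analysis surface of a paired-timepoint AAA cohort:
#'
#' * `change_table` — per variable: CT1 and CT2 median \[IQR\], the
#'   median \[IQR\] of per-patient absolute changes, the median of
#'   per-patient percent changes (CT1 denominator; patients with CT1
#'   value 0 excluded for that variable with a count), the paired
#'   Wilcoxon p-value, and the median \[IQR\] of per-patient changes
#'   normalised per 12 months.
#' * `corr_changes` — Pearson r / p of the age change and every
#'   variable's absolute change against the absolute PWS and PWRI
#'   changes.
#' * `corr_motion` — Pearson r / p of the three maximum-point motion
#'   distances against every absolute change.
#' * `group_comparison` — for each motion distance, patients are split
#'   at its median (ties to the low-motion group) and every variable's
#'   absolute change is compared between the groups by rank-sum test.
#'
#' No multiplicity correction is applied by default; a
#' Benjamini-Hochberg column can be added as a clearly-labelled
#' extension via `bh_adjust = TRUE`.
#'
#' @param records data.frame with columns `patient_id`,
#'   `interval_months`, optionally `age_at_operation`, paired columns
#'   `<variable>_ct1` / `<variable>_ct2`, and motion columns
#'   `motion_max_ilt_mm`, `motion_max_pws_mm`, `motion_max_pwri_mm`
#'   (motion columns optional).
#' @param alpha significance flag level.
#' @param bh_adjust add Benjamini-Hochberg adjusted p columns
#'   (extension; the primary columns stay uncorrected).
#' @return Object of class `cohort_tables`: the four data.frames plus a
#'   `conventions` list.
#' @export
build_cohort_tables <- function(records, alpha = 0.05, bh_adjust = FALSE) {
  records <- as.data.frame(records)
  if (nrow(records) < 3L) {
    stop("need at least 3 patient records", call. = FALSE)
  }
  vars <- record_variables(records)
  if (!length(vars)) stop("no <variable>_ct1/_ct2 column pairs found",
                          call. = FALSE)
  interval <- records$interval_months

  deltas <- lapply(setNames(vars, vars), function(v) {
    records[[paste0(v, "_ct2")]] - records[[paste0(v, "_ct1")]]
  })

  change_rows <- lapply(vars, function(v) {
    ct1 <- records[[paste0(v, "_ct1")]]
    ct2 <- records[[paste0(v, "_ct2")]]
    d <- deltas[[v]]
    nz <- !is.na(ct1) & ct1 != 0
    pct <- rep(NA_real_, length(d))
    pct[nz] <- 100 * d[nz] / ct1[nz]
    wlc <- wilcoxon_signed_rank(ct1, ct2)
    dm <- median_iqr(d); nm <- median_iqr(normalize_per_12_months(d, interval))
    data.frame(
      variable = v,
      ct1 = fmt_miqr(ct1), ct2 = fmt_miqr(ct2),
      delta_abs_median = dm$median, delta_abs_q1 = dm$q1,
      delta_abs_q3 = dm$q3,
      delta_pct_median = if (all(is.na(pct))) NA_real_ else
        median_iqr(pct)$median,
      n_pct_excluded = sum(!nz),
      p_wilcoxon = wlc$p_value,
      degenerate = wlc$degenerate,
      significant = !wlc$degenerate & wlc$p_value < alpha,
      norm12_median = nm$median, norm12_q1 = nm$q1, norm12_q3 = nm$q3)
  })
  change_table <- do.call(rbind, change_rows)

  d_age <- if ("age_at_operation" %in% names(records)) {
    interval / 12  # years elapsed between studies
  } else NULL
  corr_predictors <- c(if (!is.null(d_age)) list(age_at_operation = d_age),
                       deltas[setdiff(vars, c("pws_kpa", "pwri"))])
  safe_cor <- function(x, y) {
    tryCatch({
      ct <- pearson_cor(x, y)
      c(ct$r, ct$p_value)
    }, error = function(e) c(NA_real_, NA_real_))
  }
  corr_changes <- do.call(rbind, lapply(names(corr_predictors), function(v) {
    out <- lapply(c("pws_kpa", "pwri"), function(resp) {
      if (!resp %in% names(deltas)) return(c(NA_real_, NA_real_))
      safe_cor(corr_predictors[[v]], deltas[[resp]])
    })
    data.frame(variable = v,
               r_delta_pws = out[[1L]][1L], p_delta_pws = out[[1L]][2L],
               r_delta_pwri = out[[2L]][1L], p_delta_pwri = out[[2L]][2L])
  }))
  corr_changes$significant_pws <- corr_changes$p_delta_pws < alpha
  corr_changes$significant_pwri <- corr_changes$p_delta_pwri < alpha

  motion_cols <- intersect(c("motion_max_ilt_mm", "motion_max_pws_mm",
                             "motion_max_pwri_mm"), names(records))
  corr_motion <- NULL
  group_comparison <- NULL
  if (length(motion_cols)) {
    motion_predictors <- c(if (!is.null(d_age))
      list(age_at_operation = d_age), deltas)
    corr_motion <- do.call(rbind, lapply(names(motion_predictors),
                                         function(v) {
      row <- data.frame(variable = v)
      for (mc in motion_cols) {
        ct <- safe_cor(motion_predictors[[v]], records[[mc]])
        row[[paste0("r_", mc)]] <- ct[1L]
        row[[paste0("p_", mc)]] <- ct[2L]
      }
      row
    }))
    group_comparison <- do.call(rbind, lapply(motion_cols, function(mc) {
      md <- median(records[[mc]], na.rm = TRUE)
      high <- records[[mc]] > md  # ties at the median go to "low"
      do.call(rbind, lapply(vars, function(v) {
        rs <- rank_sum_test(deltas[[v]][high], deltas[[v]][!high])
        data.frame(motion = mc, variable = v,
                   n_high = sum(high, na.rm = TRUE),
                   n_low = sum(!high, na.rm = TRUE),
                   p_rank_sum = rs$p_value,
                   significant = rs$p_value < alpha)
      }))
    }))
  }

  if (bh_adjust) {
    change_table$p_wilcoxon_bh <- stats::p.adjust(change_table$p_wilcoxon,
                                                  "BH")
    corr_changes$p_delta_pws_bh <- stats::p.adjust(corr_changes$p_delta_pws,
                                                   "BH")
    corr_changes$p_delta_pwri_bh <- stats::p.adjust(corr_changes$p_delta_pwri,
                                                    "BH")
  }

  structure(list(
    change_table = change_table,
    corr_changes = corr_changes,
    corr_motion = corr_motion,
    group_comparison = group_comparison,
    conventions = list(
      alpha = alpha,
      quantile_type = 7,
      percent_change_denominator = "ct1",
      normalisation = "per-patient delta * 12 / interval_months",
      multiplicity_correction = if (bh_adjust)
        "Benjamini-Hochberg (extension columns)" else "none",
      median_split_ties = "low group")
  ), class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables>\n")
  cat(" change_table:", nrow(x$change_table), "variables;",
      sum(x$change_table$significant), "significant at alpha =",
      x$conventions$alpha, "\n")
  if (!is.null(x$corr_motion)) {
    cat(" corr_motion:", nrow(x$corr_motion), "variables x",
        sum(grepl("^r_", names(x$corr_motion))), "motions\n")
  }
  invisible(x)
}

#' Write cohort tables to CSV plus a conventions JSON
#'
#' @param tables a [build_cohort_tables()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "cohort_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tables$change_table, file.path(dir, "change_table.csv"),
            row.names = FALSE)
  write.csv(tables$corr_changes, file.path(dir, "corr_changes.csv"),
            row.names = FALSE)
  if (!is.null(tables$corr_motion)) {
    write.csv(tables$corr_motion, file.path(dir, "corr_motion.csv"),
              row.names = FALSE)
    write.csv(tables$group_comparison,
              file.path(dir, "group_comparison.csv"), row.names = FALSE)
  }
  jsonlite::write_json(tables$conventions,
                       file.path(dir, "conventions.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
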