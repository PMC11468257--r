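# End-to-end study pipeline: volumes -> segmentation -> features -> the
# statistical report tables, with the exclusion rules applied and logged.

#' Run configuration
#'
#' @param input_dir directory with per-patient `<id>_suv.nii` and
#'   `<id>_voi.nii` files (`.nii.gz` also accepted).
#' @param clinical_csv path to the clinical table (columns: id, age,
#'   menopausal_status, histology, histologic_grade, molecular_subtype,
#'   ki67_pct, clinical_t, clinical_n, pcr, residual_cellularity_pct,
#'   pfs_months, event).
#' @param features_csv optional precomputed feature table; when given the
#'   imaging stage is skipped (the `stats` CLI verb).
#' @param seg a [seg_config()].
#' @param min_mtv_cm3 exclusion threshold: lesions below this volume are
#'   excluded with a machine-readable reason (default 1, the SUVpeak rule).
#' @param km_parameter feature whose ROC/Youden cutoff (for response) is
#'   reused to dichotomize the survival analysis (default `"nhoc_peak"`).
#' @param horizon_months survival-probability horizon (default 60).
#' @param out_dir directory for the report CSVs (`NULL` = don't write).
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs are simulated).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, clinical_csv = NULL,
                       features_csv = NULL, seg = seg_config(),
                       min_mtv_cm3 = 1, km_parameter = "nhoc_peak",
                       horizon_months = 60, out_dir = NULL, seed = 1L) {
  structure(list(input_dir = input_dir, clinical_csv = clinical_csv,
                 features_csv = features_csv, seg = seg,
                 min_mtv_cm3 = min_mtv_cm3, km_parameter = km_parameter,
                 horizon_months = horizon_months, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

PET_PARAMETERS <- c("suv_max", "suv_peak", "mtv_cm3", "tlg",
                    "nhoc_max", "nhoc_peak", "nhop_max", "nhop_peak")
GEOM_PARAMETERS <- c("nhoc_max", "nhoc_peak", "nhop_max", "nhop_peak")

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

# Table-2 analog: median (IQR) of each geometry parameter by clinical factor,
# with the rank-test p-value (Mann-Whitney for 2 levels, Kruskal-Wallis
# beyond).
group_comparison_table <- function(tab) {
  tab$triple_negative <- ifelse(tab$molecular_subtype == "Triple negative",
                                "Triple negative", "Others")
  tab$pathological_response <- ifelse(tab$pcr, "Complete responder",
                                      "Non-responder")
  factors <- c("histology", "histologic_grade", "molecular_subtype",
               "triple_negative", "clinical_t", "clinical_n",
               "pathological_response")
  out <- list()
  for (f in factors) {
    g <- tab[[f]]
    lv <- unique(stats::na.omit(g))
    if (length(lv) < 2L) next
    for (p in GEOM_PARAMETERS) {
      pv <- tryCatch(rank_tests(tab[[p]], g)$p_value, error = function(e) NA_real_)
      for (l in sort(lv)) {
        out[[length(out) + 1L]] <- data.frame(
          factor = f, level = l, parameter = p,
          median_iqr = median_iqr(tab[[p]][g == l]),
          p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

roc_table <- function(tab) {
  do.call(rbind, lapply(PET_PARAMETERS, function(p) {
    r <- roc_youden(tab[[p]], tab$pcr)
    data.frame(parameter = p, auc = r$auc,
               auc_ci_lo = r$auc_ci95[1], auc_ci_hi = r$auc_ci95[2],
               cutoff = r$cutoff, sensitivity_pct = r$sensitivity_pct,
               specificity_pct = r$specificity_pct, direction = r$direction,
               stringsAsFactors = FALSE)
  }))
}

model_table <- function(tab, fitter) {
  # non-convergence is recorded in the `converged` column, not as a warning
  uni <- lapply(PET_PARAMETERS, function(p) {
    tryCatch(suppressWarnings(fitter(tab, p, adjusted = FALSE)),
             error = function(e) NULL)
  })
  rows <- list()
  for (i in seq_along(PET_PARAMETERS)) {
    m <- uni[[i]]
    if (is.null(m)) next
    row <- data.frame(parameter = m$parameter, p_value = m$p_value,
                      effect = m$effect, ci_lo = m$ci95[1], ci_hi = m$ci95[2],
                      adjusted = FALSE, converged = m$converged,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- row
    # the paper's design: univariately significant parameters are refit, one
    # at a time, with the fixed clinical covariates
    if (is.finite(m$p_value) && m$p_value < 0.05) {
      mm <- tryCatch(suppressWarnings(fitter(tab, m$parameter, adjusted = TRUE)),
                     error = function(e) NULL)
      if (!is.null(mm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = mm$parameter, p_value = mm$p_value, effect = mm$effect,
          ci_lo = mm$ci95[1], ci_hi = mm$ci95[2], adjusted = TRUE,
          converged = mm$converged, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Statistical battery on a merged feature + clinical table
#'
#' Produces the report tables (group comparisons, ROC, logistic, Cox,
#' Kaplan-Meier) from a table that already joins the extracted features with
#' the clinical outcomes. The Kaplan-Meier grouping reuses the ROC/Youden
#' cutoff of `km_parameter` for response, as the study chains them.
#'
#' @param tab merged data.frame (feature columns + PatientRecord columns).
#' @param km_parameter,horizon_months see [run_config()].
#' @return list with `group_comparison`, `roc`, `logistic`, `cox`, `km`
#'   (curve table), `km_summary`.
#' @export
study_statistics <- function(tab, km_parameter = "nhoc_peak",
                             horizon_months = 60) {
  tab <- coerce_cohort(tab)
  roc <- roc_table(tab)
  km_cut <- roc$cutoff[roc$parameter == km_parameter]
  km <- tryCatch(km_logrank(tab, km_parameter, km_cut, horizon_months),
                 error = function(e) NULL)
  list(group_comparison = group_comparison_table(tab),
       roc = roc,
       logistic = model_table(tab, logistic_or),
       cox = model_table(tab, cox_hr),
       km = if (!is.null(km)) km$curves else NULL,
       km_summary = km)
}

#' Run the full study pipeline
#'
#' Imaging stage (unless `features_csv` is given): for every patient in the
#' clinical table, load `<id>_suv.nii`/`<id>_voi.nii`, segment with the
#' adaptive threshold, and extract the eight PET parameters; patients whose
#' lesion fails a rule are excluded with a machine-readable reason (e.g.
#' `"MTV < 1 cm^3"`). Statistics stage: [study_statistics()] on the merged
#' table. Deterministic given config and inputs.
#'
#' @param config a [run_config()].
#' @return list of class `study_report`: `features`, `exclusions`, the
#'   statistics tables, and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$clinical_csv) || !file.exists(config$clinical_csv)) {
    stop("clinical_csv is required and must exist", call. = FALSE)
  }
  clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
  if (!"id" %in% names(clinical)) stop("clinical table has no 'id' column", call. = FALSE)

  exclusions <- data.frame(id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (is.null(config$features_csv)) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stop("input_dir is required for the imaging stage", call. = FALSE)
    }
    find_file <- function(stem) {
      for (ext in c(".nii", ".nii.gz")) {
        f <- file.path(config$input_dir, paste0(stem, ext))
        if (file.exists(f)) return(f)
      }
      NA_character_
    }
    rows <- list()
    for (id in clinical$id) {
      fv <- find_file(paste0(id, "_suv")); fm <- find_file(paste0(id, "_voi"))
      if (is.na(fv) || is.na(fm)) {
        stop("missing volume or VOI for patient '", id, "' in ",
             config$input_dir, call. = FALSE)
      }
      row <- tryCatch({
        vol <- load_suv_volume(fv)
        voi <- load_mask(fm, reference = vol)
        seg <- segment_tumor(vol, voi, cfg = config$seg)
        mtv <- sum(seg$mask$values) * voxel_volume_mm3(vol) / 1000
        if (mtv < config$min_mtv_cm3) {
          stop(sprintf("MTV < %g cm^3", config$min_mtv_cm3), call. = FALSE)
        }
        conv <- conventional_features(vol, seg$mask,
                                      peak_sphere_volume_cm3 = config$min_mtv_cm3)
        geo <- hotspot_geometry(vol, seg$mask, conv)
        data.frame(id = id, suv_max = conv$suv_max, suv_peak = conv$suv_peak,
                   mtv_cm3 = conv$mtv_cm3, tlg = conv$tlg,
                   nhoc_max = geo$nhoc_max, nhoc_peak = geo$nhoc_peak,
                   nhop_max = geo$nhop_max, nhop_peak = geo$nhop_peak,
                   threshold_suv = seg$threshold_suv, stringsAsFactors = FALSE)
      }, error = function(e) conditionMessage(e))
      if (is.character(row)) {
        exclusions <- rbind(exclusions,
                            data.frame(id = id, reason = row,
                                       stringsAsFactors = FALSE))
      } else {
        rows[[length(rows) + 1L]] <- row
      }
    }
    features <- do.call(rbind, rows)
  } else {
    features <- utils::read.csv(config$features_csv, stringsAsFactors = FALSE)
  }
  if (is.null(features) || nrow(features) == 0L) {
    stop("all patients excluded; nothing to analyse", call. = FALSE)
  }
  # statistics consume the EXTRACTED features: if the clinical table carries
  # feature columns of the same names (e.g. a simulated cohort file), drop
  # them in favour of the imaging-derived values
  dup <- intersect(setdiff(names(features), "id"), names(clinical))
  clinical <- clinical[, setdiff(names(clinical), dup), drop = FALSE]
  tab <- merge(features, clinical, by = "id", sort = TRUE)
  if (nrow(tab) == 0L) {
    stop("no overlap between imaging and clinical patient ids", call. = FALSE)
  }
  stats_tabs <- study_statistics(tab, config$km_parameter,
                                 config$horizon_months)
  manifest <- c(
    sprintf("seed = %s", config$seed),
    sprintf("n_analysed = %d", nrow(tab)),
    sprintf("n_excluded = %d", nrow(exclusions)),
    sprintf("segmentation = nestle slope %.2f, hot fraction %.2f, shell %g-%g mm, %d-conn",
            config$seg$threshold_slope, config$seg$high_uptake_fraction,
            config$seg$background_shell_mm[1], config$seg$background_shell_mm[2],
            config$seg$connectivity),
    sprintf("km_parameter = %s (cutoff %.4g)", config$km_parameter,
            stats_tabs$roc$cutoff[stats_tabs$roc$parameter == config$km_parameter]),
    sprintf("horizon_months = %g", config$horizon_months))

  report <- structure(list(features = tab, exclusions = exclusions,
                           group_comparison = stats_tabs$group_comparison,
                           roc = stats_tabs$roc, logistic = stats_tabs$logistic,
                           cox = stats_tabs$cox, km = stats_tabs$km,
                           km_summary = stats_tabs$km_summary,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Write the report tables of a study run as CSV files
#' @param report a `study_report` from [run_study()].
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wr(report$features, "features.csv")
  wr(report$exclusions, "exclusions.csv")
  wr(report$group_comparison, "group_comparison.csv")
  wr(report$roc, "roc.csv")
  wr(report$logistic, "logistic.csv")
  wr(report$cox, "cox.csv")
  wr(report$km, "km_curves.csv")
  writeLines(report$manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d patients analysed, %d excluded\n",
              nrow(x$features), nrow(x$exclusions)))
  cat("  ROC (response prediction):\n")
  r <- x$roc
  for (i in seq_len(nrow(r))) {
    cat(sprintf("    %-10s AUC %.3f (%.3f-%.3f)  cutoff %s%.3g  sens %.1f%%  spec %.1f%%\n",
                r$parameter[i], r$auc[i], r$auc_ci_lo[i], r$auc_ci_hi[i],
                r$direction[i], r$cutoff[i], r$sensitivity_pct[i],
                r$specificity_pct[i]))
  }
  if (!is.null(x$km_summary)) {
    cat(sprintf("  KM at %s cutoff %.3g: log-rank p = %.4g\n",
                "response", x$km_summary$cutoff, x$km_summary$logrank_p))
  }
  invisible(x)
}
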