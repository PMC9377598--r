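#' Configuration of a full pipeline run
#'
#' Points the pipeline at its inputs and fixes the analysis settings. Exactly
#' one of `curves_csv` (pre-computed volume-time curves) or `masks_dir`
#' (a directory of 4D NIfTI masks, one file per patient) must be given.
#'
#' @param clinical_path CSV or XLSX clinical table; see [read_clinical()].
#' @param curves_csv path to a curve CSV (see [read_curves_csv()]).
#' @param masks_dir directory containing `*.nii`/`*.nii.gz` masks.
#' @param clinical_mapping optional column mapping for [read_clinical()].
#' @param detection an [detect_config()].
#' @param subset `"sinus_only"` restricts the statistics stage to patients
#'   with a complete sinus detection and analyses all three emptying
#'   fractions; `"comprehensive"` keeps AF-mode patients and analyses the
#'   totals-only quantities (total emptying fraction, max/min volumes).
#' @param groupings grouping columns for [compare_groups()].
#' @param candidates candidate predictors for [fit_mlrm_stepwise()].
#' @param forced forced covariates for the regression stage.
#' @param out_dir optional output directory; when given, per-stage CSVs, an
#'   exclusion log and a JSON results bundle are written.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return An object of class `la_run_config`.
#' @export
run_config <- function(clinical_path, curves_csv = NULL, masks_dir = NULL,
                       clinical_mapping = NULL,
                       detection = detect_config(),
                       subset = c("sinus_only", "comprehensive"),
                       groupings = c("stroke_risk", "afbs_category",
                                     "af_type", "ehra"),
                       candidates = c("af_persistent", "afbs", "ehra",
                                      "cha2ds2vasc", "hypertension",
                                      "diabetes", "heart_failure",
                                      "renal_failure", "lvef"),
                       forced = c("age", "male_sex", "bmi"),
                       out_dir = NULL, seed = NULL) {
  subset <- match.arg(subset)
  if (is.null(curves_csv) == is.null(masks_dir)) {
    stop("give exactly one of `curves_csv` or `masks_dir` (configuration error)",
         call. = FALSE)
  }
  for (p in c(clinical_path, curves_csv, masks_dir)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist (configuration error): ", p, call. = FALSE)
    }
  }
  structure(
    list(clinical_path = clinical_path, curves_csv = curves_csv,
         masks_dir = masks_dir, clinical_mapping = clinical_mapping,
         detection = detection, subset = subset, groupings = groupings,
         candidates = candidates, forced = forced, out_dir = out_dir,
         seed = seed),
    class = "la_run_config"
  )
}

#' Run the full LA function pipeline
#'
#' Orchestrates volumetry (when masks are given), fiducial detection, LA
#' function computation, clinical scoring and the cohort statistics stage.
#' Per-patient failures (rejected curves, missing clinical rows) are logged
#' and excluded, never aborting the batch; patient counts are conserved:
#' analyzable + comprehensive-only + excluded equals the input count.
#'
#' @param config an [run_config()].
#' @return A list of class `la_run_result` with elements `curves`,
#'   `detection` (output of [batch_detect()]), `cohort` (the analysis
#'   table), `exclusions` (data.frame of patient_id/reason), `counts`
#'   (named: analyzable, comprehensive_only, excluded, input), `comparisons`
#'   (per grouping, lists from [compare_groups()]) and `models` (per
#'   outcome, [fit_mlrm_stepwise()] results). Written to `out_dir` when
#'   configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "la_run_config"))

  ## stage 1: curves
  curves <- if (!is.null(config$curves_csv)) {
    read_curves_csv(config$curves_csv)
  } else {
    files <- list.files(config$masks_dir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files)) {
      stop("no NIfTI masks found in ", config$masks_dir, call. = FALSE)
    }
    series <- lapply(files, read_mask_nifti)
    cs <- lapply(series, build_curve)
    names(cs) <- vapply(cs, `[[`, character(1), "patient_id")
    cs
  }
  n_input <- length(curves)

  ## stage 2: fiducials
  det <- batch_detect(curves, config$detection)
  ftab <- fiducials_table(det$fiducials)

  ## stage 3: clinical + scores
  clinical <- read_clinical(config$clinical_path, config$clinical_mapping)
  if (!"patient_id" %in% names(clinical)) {
    stop("clinical table must have a `patient_id` column", call. = FALSE)
  }
  clinical <- score_cohort(clinical)
  if (!"bsa" %in% names(clinical)) {
    if (!all(c("height", "weight") %in% names(clinical))) {
      stop("clinical table needs `bsa` or `height`+`weight`", call. = FALSE)
    }
    clinical$bsa <- bsa_mosteller(clinical$height, clinical$weight)
  }
  if (!"bmi" %in% names(clinical) &&
      all(c("height", "weight") %in% names(clinical))) {
    clinical$bmi <- clinical$weight / (clinical$height / 100)^2
  }

  ## stage 4: per-patient LA function, with exclusion bookkeeping
  exclusions <- data.frame(patient_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  results <- list()
  for (pid in names(det$fiducials)) {
    fid <- det$fiducials[[pid]]
    if (fid$mode == "rejected") {
      exclusions <- rbind(exclusions, data.frame(
        patient_id = pid, reason = fid$rejection_reason,
        stringsAsFactors = FALSE))
      next
    }
    row <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (nrow(row) != 1L) {
      exclusions <- rbind(exclusions, data.frame(
        patient_id = pid, reason = "missing clinical record",
        stringsAsFactors = FALSE))
      next
    }
    results[[pid]] <- la_function(fid, bsa = row$bsa[1])
  }
  if (!length(results)) stop("no analyzable patients remain", call. = FALSE)
  lf <- la_function_table(results)
  cohort <- merge(lf, clinical, by = "patient_id",
                  suffixes = c("", ".clinical"))
  cohort$male_sex <- as.integer(cohort$sex == "male")
  cohort$af_persistent <- as.integer(cohort$af_type == "persistent")
  cohort$ehra <- as.numeric(cohort$ehra)

  counts <- c(
    analyzable = sum(cohort$mode == "sinus_complete"),
    comprehensive_only = sum(cohort$mode == "af_no_preA"),
    excluded = n_input - nrow(cohort),
    input = n_input
  )

  ## stage 5: statistics on the configured subset
  if (config$subset == "sinus_only") {
    stat_tab <- cohort[cohort$mode == "sinus_complete", , drop = FALSE]
    outcomes <- c("laef_total", "laef_active", "laef_passive")
    variables <- c(outcomes, "v_max", "v_min", "v_preA", "v_min2",
                   "lavi_max", "lavi_min", "lavi_preA", "lavi_min2")
  } else {
    stat_tab <- cohort
    outcomes <- "laef_total"
    variables <- c("laef_total", "v_max", "v_min", "lavi_max", "lavi_min")
  }
  comparisons <- list()
  for (g in intersect(config$groupings, names(stat_tab))) {
    lv <- unique(stat_tab[[g]][!is.na(stat_tab[[g]])])
    if (length(lv) < 2) next
    comparisons[[g]] <- tryCatch(
      suppressWarnings(compare_groups(stat_tab, g, variables)),
      error = function(e) e$message
    )
  }
  models <- list()
  cand <- intersect(config$candidates, names(stat_tab))
  for (oc in outcomes) {
    models[[oc]] <- tryCatch(
      suppressWarnings(fit_mlrm_stepwise(stat_tab, oc, cand,
                                         forced = config$forced)),
      error = function(e) e$message
    )
  }

  result <- structure(
    list(curves = curves, detection = det, fiducials = ftab,
         cohort = cohort, exclusions = exclusions, counts = counts,
         comparisons = comparisons, models = models, config = config),
    class = "la_run_result"
  )
  if (!is.null(config$out_dir)) write_run_result(result, config$out_dir)
  result
}

#' @export
print.la_run_result <- function(x, ...) {
  cat("<la_run_result>\n")
  cat(sprintf(
    "  patients: %d input = %d analyzable + %d comprehensive-only + %d excluded\n",
    x$counts[["input"]], x$counts[["analyzable"]],
    x$counts[["comprehensive_only"]], x$counts[["excluded"]]
  ))
  cat(sprintf("  subset: %s; %d group comparisons, %d regression models\n",
              x$config$subset, length(x$comparisons), length(x$models)))
  invisible(x)
}

write_run_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_curves_csv(result$curves, file.path(out_dir, "curves.csv"))
  write.csv(result$fiducials, file.path(out_dir, "fiducials.csv"),
            row.names = FALSE)
  write.csv(result$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(result$exclusions, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)
  stats_bundle <- list(
    counts = as.list(result$counts),
    comparisons = lapply(result$comparisons, function(grp) {
      if (is.character(grp)) return(grp)
      lapply(grp, function(cmp) list(
        variable = cmp$variable, test = cmp$test, p_value = cmp$p_value,
        descriptives = cmp$descriptives, posthoc = cmp$posthoc
      ))
    }),
    models = lapply(result$models, function(m) {
      if (is.character(m)) return(m)
      list(outcome = m$outcome, adjusted_r2 = m$adjusted_r2,
           terms = m$terms, excluded_terms = m$excluded_terms)
    }),
    run = list(
      subset = result$config$subset,
      seed = result$config$seed,
      detection = unclass(result$config$detection),
      package_version = as.character(utils::packageVersion("laef"))
    )
  )
  jsonlite::write_json(stats_bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
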