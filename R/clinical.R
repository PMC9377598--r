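#' AF Burden score
#'
#' A structured clinical severity score for atrial fibrillation summing
#' points for episode frequency, episode duration and the number of
#' electrical cardioversions:
#' \itemize{
#'   \item frequency: daily = 5, two or more days a week = 4, once a week =
#'     3, monthly = 2, fewer than 4 times per year = 1;
#'   \item duration: minutes = 1, hours = 2, most of the day = 3, all day = 4;
#'   \item cardioversions: none = 0, 1 = 1, 2 = 2, 3 = 3, more than 3 = 4.
#' }
#' The total is binned as minimal (1-3), mild (4-6), moderate (7-9) and
#' severe (>= 10), with ordinal codes 1-4. With the frequency and duration
#' components starting at one point each, the smallest attainable total is 2.
#'
#' @param frequency one of `"daily"`, `"ge2_per_week"`, `"weekly"`,
#'   `"monthly"`, `"lt4_per_year"` (vectorised).
#' @param duration one of `"minutes"`, `"hours"`, `"most_of_day"`,
#'   `"all_day"`.
#' @param n_cardioversions non-negative integer count of electrical
#'   cardioversions.
#' @return A data.frame with columns `frequency_points`, `duration_points`,
#'   `cardioversion_points`, `total`, `category` (factor
#'   minimal/mild/moderate/severe) and `category_code` (1-4).
#' @export
#' @examples
#' afbs("monthly", "hours", 1) # total 5, mild
afbs <- function(frequency, duration, n_cardioversions) {
  freq_map <- c(lt4_per_year = 1L, monthly = 2L, weekly = 3L,
                ge2_per_week = 4L, daily = 5L)
  dur_map <- c(minutes = 1L, hours = 2L, most_of_day = 3L, all_day = 4L)
  if (!all(frequency %in% names(freq_map))) {
    stop("unknown episode frequency category (invalid category)", call. = FALSE)
  }
  if (!all(duration %in% names(dur_map))) {
    stop("unknown episode duration category (invalid category)", call. = FALSE)
  }
  n_cardioversions <- as.integer(n_cardioversions)
  if (anyNA(n_cardioversions) || any(n_cardioversions < 0)) {
    stop("`n_cardioversions` must be a non-negative integer", call. = FALSE)
  }
  fp <- unname(freq_map[frequency])
  dp <- unname(dur_map[duration])
  cp <- pmin(n_cardioversions, 4L)
  total <- fp + dp + cp
  code <- ifelse(total <= 3L, 1L, ifelse(total <= 6L, 2L, ifelse(total <= 9L, 3L, 4L)))
  levels <- c("minimal", "mild", "moderate", "severe")
  data.frame(
    frequency_points = fp, duration_points = dp, cardioversion_points = cp,
    total = total,
    category = factor(levels[code], levels = levels),
    category_code = code,
    stringsAsFactors = FALSE
  )
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Standard additive score: congestive heart failure 1, hypertension 1,
#' age >= 75 years 2, diabetes 1, prior stroke or TIA 2, vascular disease 1,
#' age 65-74 years 1, female sex 1. All arguments are vectorised.
#'
#' @param age age in years.
#' @param sex `"female"` or `"male"`.
#' @param heart_failure,hypertension,diabetes,prior_stroke_or_tia,vascular_disease
#'   logical comorbidity flags.
#' @return Integer score(s) in 0-9.
#' @export
#' @examples
#' cha2ds2vasc(76, "female", FALSE, TRUE, TRUE, TRUE, FALSE) # 7
cha2ds2vasc <- function(age, sex, heart_failure, hypertension, diabetes,
                        prior_stroke_or_tia, vascular_disease) {
  if (anyNA(age) || any(age <= 0)) {
    stop("`age` must be positive (incomplete profile)", call. = FALSE)
  }
  if (!all(sex %in% c("female", "male"))) {
    stop("`sex` must be \"female\" or \"male\" (incomplete profile)",
         call. = FALSE)
  }
  flags <- list(heart_failure, hypertension, diabetes,
                prior_stroke_or_tia, vascular_disease)
  if (any(vapply(flags, anyNA, logical(1)))) {
    stop("comorbidity flags must not be NA (incomplete profile)", call. = FALSE)
  }
  age_pts <- ifelse(age >= 75, 2L, ifelse(age >= 65, 1L, 0L))
  as.integer(
    age_pts + (sex == "female") + heart_failure + hypertension + diabetes +
      2L * prior_stroke_or_tia + vascular_disease
  )
}

#' Stroke-risk group from a CHA2DS2-VASc score
#'
#' Scores of 0 or 1 are classified as low risk, scores of 2 or more as
#' increased risk.
#'
#' @param score non-negative integer score(s).
#' @return Factor with levels `"low"`, `"increased"`.
#' @export
stroke_risk_group <- function(score) {
  if (anyNA(score) || any(score < 0)) {
    stop("`score` must be non-negative (invalid score)", call. = FALSE)
  }
  factor(ifelse(score >= 2, "increased", "low"), levels = c("low", "increased"))
}

#' Append AF classification scores to a clinical table
#'
#' Computes the AF Burden score components, the CHA2DS2-VASc score and the
#' stroke-risk group for each row of a clinical table. Vascular disease is
#' taken from a `vascular_disease` column when present, otherwise from a
#' `myocardial_infarction` flag. EHRA class and AF type are carried through
#' unchanged.
#'
#' @param clinical data.frame with columns `patient_id`, `age`, `sex`,
#'   `episode_frequency`, `episode_duration`, `n_cardioversions` and the
#'   comorbidity flags `heart_failure`, `hypertension`, `diabetes`,
#'   `prior_stroke_or_tia` (or `stroke`), and `vascular_disease` (or
#'   `myocardial_infarction`).
#' @return The input data.frame with appended columns `afbs_total`,
#'   `afbs_category`, `afbs` (ordinal code 1-4), `cha2ds2vasc` and
#'   `stroke_risk`.
#' @export
score_cohort <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  stroke_col <- if ("prior_stroke_or_tia" %in% names(clinical)) {
    clinical$prior_stroke_or_tia
  } else if ("stroke" %in% names(clinical)) {
    clinical$stroke
  } else {
    stop("clinical table needs `prior_stroke_or_tia` or `stroke`", call. = FALSE)
  }
  vasc_col <- if ("vascular_disease" %in% names(clinical)) {
    clinical$vascular_disease
  } else if ("myocardial_infarction" %in% names(clinical)) {
    clinical$myocardial_infarction
  } else {
    stop("clinical table needs `vascular_disease` or `myocardial_infarction`",
         call. = FALSE)
  }
  b <- afbs(clinical$episode_frequency, clinical$episode_duration,
            clinical$n_cardioversions)
  clinical$afbs_total <- b$total
  clinical$afbs_category <- b$category
  clinical$afbs <- b$category_code
  clinical$cha2ds2vasc <- cha2ds2vasc(
    clinical$age, clinical$sex,
    as.logical(clinical$heart_failure), as.logical(clinical$hypertension),
    as.logical(clinical$diabetes), as.logical(stroke_col),
    as.logical(vasc_col)
  )
  clinical$stroke_risk <- stroke_risk_group(clinical$cha2ds2vasc)
  clinical
}

#' Read a clinical table from CSV or XLSX
#'
#' Columns can be renamed to the package's expected schema through an
#' explicit mapping rather than guessed: `mapping` is a named character
#' vector `c(expected_name = "column name in file", ...)`. Reading `.xlsx`
#' requires the optional readxl package.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @param mapping optional named character vector renaming file columns to
#'   the expected schema (see [score_cohort()] for expected names).
#' @param sheet sheet name or index for XLSX input.
#' @return A data.frame.
#' @export
read_clinical <- function(path, mapping = NULL, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(mapping)) {
    missing <- setdiff(unname(mapping), names(df))
    if (length(missing)) {
      stop("mapped columns not found in file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (target in names(mapping)) {
      names(df)[names(df) == mapping[[target]]] <- target
    }
  }
  df
}
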