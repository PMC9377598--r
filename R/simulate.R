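#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators do not disturb the global random stream.
#' A `NULL` seed runs the code on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Parameters of a synthetic sinus-rhythm volume-time curve
#'
#' Describes the biphasic LA cycle: reservoir filling from the minimum at
#' the R-wave up to `v_max`, passive (conduit) emptying down to the
#' diastasis volume `v_min2`, a small filling rebound up to the
#' pre-contraction volume `v_preA`, and active (booster-pump) emptying back
#' to `v_min` at the end of the cycle.
#'
#' @param v_max,v_min,v_preA,v_min2 fiducial volumes in ml with
#'   `v_min <= v_min2 <= v_preA <= v_max`.
#' @param phase_fractions length-3 numeric `(t_max, t_min2, t_preA)`,
#'   strictly increasing fractions of the cycle in (0, 1) at which the
#'   respective fiducials occur.
#' @param n_frames frames per cardiac cycle (default 25).
#' @param noise_sd additive Gaussian noise SD in ml (default 0).
#' @param patient_id identifier carried onto the curve.
#' @return An object of class `la_curve_params`.
#' @export
curve_params <- function(v_max = 100, v_min = 50, v_preA = 80, v_min2 = 75,
                         phase_fractions = c(t_max = 0.36, t_min2 = 0.64,
                                             t_preA = 0.80),
                         n_frames = 25L, noise_sd = 0,
                         patient_id = "synthetic") {
  if (!(v_min <= v_min2 && v_min2 <= v_preA && v_preA <= v_max)) {
    stop("volumes must satisfy v_min <= v_min2 <= v_preA <= v_max (invalid params)",
         call. = FALSE)
  }
  pf <- as.numeric(phase_fractions)
  if (length(pf) != 3 || any(pf <= 0) || any(pf >= 1) || any(diff(pf) <= 0)) {
    stop("phase fractions must be strictly increasing in (0, 1) (invalid params)",
         call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 5L) stop("`n_frames` must be >= 5 (invalid params)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0 (invalid params)", call. = FALSE)
  idx <- as.integer(round(pf * n_frames))
  if (idx[1] < 1L || any(diff(idx) < 2L) || idx[3] > n_frames - 2L) {
    stop("phase fractions too close together for the frame grid (invalid params)",
         call. = FALSE)
  }
  structure(
    list(v_max = v_max, v_min = v_min, v_preA = v_preA, v_min2 = v_min2,
         phase_fractions = pf, i_max = idx[1], i_min2 = idx[2],
         i_preA = idx[3], n_frames = n_frames, noise_sd = noise_sd,
         patient_id = patient_id),
    class = "la_curve_params"
  )
}

# half-cosine ramp between (f0, v0) and (f1, v1), evaluated at integer frames
# f0..f1; endpoint-exact and C1 at the joins (zero slope at both ends).
cos_ramp <- function(f0, f1, v0, v1) {
  f <- f0:f1
  v0 + (v1 - v0) * (1 - cos(pi * (f - f0) / (f1 - f0))) / 2
}

#' Simulate a sinus-rhythm LA volume-time curve
#'
#' Generates a piecewise-cosine curve through the four fiducial volumes at
#' their phase frames (segments are extremum-exact: the noiseless curve
#' attains each parameter exactly at its frame, with the minimum at both
#' ends of the cycle). Gaussian noise is added when `noise_sd > 0`.
#'
#' @param params an [curve_params()] object.
#' @param seed optional integer seed (same seed, same curve).
#' @return A list with `curve` (the [la_curve]) and `truth`, an
#'   `la_fiducials` carrying the generator's ground-truth indices and
#'   volumes (mode `"sinus_complete"`; the minimum sits at the cycle wrap,
#'   `i_min = 0`).
#' @export
#' @examples
#' sim <- simulate_curve(curve_params())
#' detect_fiducials(sim$curve)
simulate_curve <- function(params, seed = NULL) {
  stopifnot(inherits(params, "la_curve_params"))
  n <- params$n_frames
  v <- numeric(n)
  i1 <- params$i_max; i2 <- params$i_min2; i3 <- params$i_preA
  v[1:(i1 + 1)] <- cos_ramp(0, i1, params$v_min, params$v_max)
  v[(i1 + 1):(i2 + 1)] <- cos_ramp(i1, i2, params$v_max, params$v_min2)
  v[(i2 + 1):(i3 + 1)] <- cos_ramp(i2, i3, params$v_min2, params$v_preA)
  # active emptying reaches v_min exactly at the cycle wrap (frame n == 0)
  v[(i3 + 1):n] <- cos_ramp(i3, n, params$v_preA, params$v_min)[1:(n - i3)]
  if (params$noise_sd > 0) {
    v <- with_seed(seed, v + rnorm(n, sd = params$noise_sd))
    v <- pmax(v, 0)
  }
  truth <- new_fiducials(
    params$patient_id, n, "sinus_complete",
    i_max = params$i_max, v_max = params$v_max,
    i_min = 0L, v_min = params$v_min,
    i_preA = params$i_preA, v_preA = params$v_preA,
    i_min2 = params$i_min2, v_min2 = params$v_min2
  )
  list(curve = la_curve(v, patient_id = params$patient_id), truth = truth)
}

#' Simulate an AF-mode LA volume-time curve
#'
#' During atrial fibrillation there is no organised atrial contraction: the
#' curve rises to its maximum and then decays monotonically back to the
#' minimum, with no diastasis rebound.
#'
#' @param v_max,v_min volumes in ml, `v_min < v_max`.
#' @param t_max fraction of the cycle at which the maximum occurs.
#' @param n_frames frames per cycle.
#' @param noise_sd additive Gaussian noise SD in ml.
#' @param seed optional integer seed.
#' @param patient_id identifier.
#' @return A list with `curve` and `truth` (mode `"af_no_preA"`).
#' @export
simulate_af_curve <- function(v_max = 100, v_min = 50, t_max = 0.36,
                              n_frames = 25L, noise_sd = 0, seed = NULL,
                              patient_id = "synthetic_af") {
  if (!(v_min < v_max)) stop("need v_min < v_max (invalid params)", call. = FALSE)
  if (t_max <= 0 || t_max >= 1) {
    stop("`t_max` must lie in (0, 1) (invalid params)", call. = FALSE)
  }
  n <- as.integer(n_frames)
  if (n < 5L) stop("`n_frames` must be >= 5 (invalid params)", call. = FALSE)
  i1 <- as.integer(round(t_max * n))
  if (i1 < 1L || i1 > n - 2L) {
    stop("`t_max` too close to the cycle boundary (invalid params)", call. = FALSE)
  }
  v <- numeric(n)
  v[1:(i1 + 1)] <- cos_ramp(0, i1, v_min, v_max)
  v[(i1 + 1):n] <- cos_ramp(i1, n, v_max, v_min)[1:(n - i1)]
  if (noise_sd > 0) {
    v <- with_seed(seed, v + rnorm(n, sd = noise_sd))
    v <- pmax(v, 0)
  }
  truth <- new_fiducials(patient_id, n, "af_no_preA",
                         i_max = i1, v_max = v_max,
                         i_min = 0L, v_min = v_min)
  list(curve = la_curve(v, patient_id = patient_id), truth = truth)
}

#' Corrupt a curve with extrasystole-like oscillations
#'
#' Premature beats during a retrospectively gated acquisition show up as
#' short spurious oscillations on the volume-time curve. Each event adds one
#' full oscillation cycle (two frames up, two frames down) at a random
#' (seeded) location; amplitude is relative to the curve's maximum volume.
#'
#' @param curve an [la_curve].
#' @param amplitude_fraction oscillation amplitude as a fraction of the
#'   curve maximum; `0` returns the curve unchanged.
#' @param n_events number of injected events.
#' @param seed optional integer seed.
#' @return The corrupted [la_curve].
#' @export
corrupt_with_extrasystoles <- function(curve, amplitude_fraction = 0.15,
                                       n_events = 2L, seed = NULL) {
  stopifnot(inherits(curve, "la_curve"))
  if (amplitude_fraction < 0) {
    stop("`amplitude_fraction` must be >= 0", call. = FALSE)
  }
  if (amplitude_fraction == 0 || n_events < 1) return(curve)
  n <- curve$n_frames
  amp <- amplitude_fraction * max(curve$volumes_ml)
  v <- with_seed(seed, {
    out <- curve$volumes_ml
    centres <- sample.int(n, n_events, replace = FALSE)
    pattern <- amp * c(1, 1, -1, -1)
    for (ctr in centres) {
      at <- ((ctr - 1L + 0:3) %% n) + 1L
      out[at] <- out[at] + pattern
    }
    out
  })
  la_curve(pmax(v, 0), patient_id = curve$patient_id,
           flag_empty_frames = curve$flag_empty_frames)
}

#' Simulate a time-resolved ellipsoid segmentation series
#'
#' Rasterises a sphere of the analytic target volume at each cardiac frame
#' onto a voxel grid (a voxel is inside if its centre is), giving a mask
#' series whose exact voxel counts are returned as ground truth for
#' volumetry tests.
#'
#' @param volumes_ml analytic target volume per frame, in ml.
#' @param dims grid dimensions (row, col, slice).
#' @param in_plane_spacing mm per pixel (row, col).
#' @param slice_thickness mm.
#' @param patient_id identifier.
#' @return A list with `series` (an `la_seg_series`, see [seg_series()]),
#'   `voxel_counts` (integer per frame) and `volumes_ml` (the analytic
#'   targets).
#' @export
simulate_mask_series <- function(volumes_ml, dims = c(48L, 48L, 24L),
                                 in_plane_spacing = c(1, 1),
                                 slice_thickness = 1,
                                 patient_id = "synthetic_mask") {
  stopifnot(length(dims) == 3, all(volumes_ml >= 0))
  if (length(in_plane_spacing) == 1L) in_plane_spacing <- rep(in_plane_spacing, 2L)
  n <- length(volumes_ml)
  mask <- array(0L, c(dims, n))
  counts <- integer(n)
  sp <- c(in_plane_spacing, slice_thickness)
  centre <- (dims + 1) / 2
  coords <- lapply(1:3, function(k) (seq_len(dims[k]) - centre[k]) * sp[k])
  for (f in seq_len(n)) {
    v_mm3 <- volumes_ml[f] * 1000
    r <- (3 * v_mm3 / (4 * pi))^(1 / 3)
    if (r > 0) {
      inside <- outer(outer(coords[[1]]^2, coords[[2]]^2, `+`),
                      coords[[3]]^2, `+`) <= r^2
      mask[, , , f] <- as.integer(inside)
      counts[f] <- sum(inside)
    }
  }
  series <- seg_series(mask, in_plane_spacing, slice_thickness,
                       patient_id = patient_id)
  list(series = series, voxel_counts = counts, volumes_ml = volumes_ml)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the covariate distributions of the study population
#' this package models (102 AF patients: age 60.8 +/- 8.9 years, 17.6%
#' female, BMI 26.8 +/- 4.0 kg/m^2, BSA 2.02 +/- 0.21 m^2, AF Burden
#' categories 8/65/23/5, hypertension 53.9%, heart failure 6.9%, diabetes
#' 6.9%, renal failure 7.8%, myocardial infarction 2.9%, stroke 6.9%,
#' LVEF 57.4 +/- 8.0%, 71.6% paroxysmal AF, maximum LA volume 102.5 +/-
#' 34.2 ml) and the published multivariable regression coefficient sets for
#' total, active and passive emptying fraction, with residual SDs
#' calibrated so that the fitted models attain the published adjusted
#' R-squared values (0.32 / 0.22 / 0.14).
#'
#' @param n_patients cohort size (>= 10).
#' @param seed integer seed or `NULL`.
#' @param age_mean,age_sd,female_p,bmi_mean,bmi_sd,bsa_mean,bsa_sd,height_mean,height_sd
#'   anthropometric distributions.
#' @param afbs_probs probabilities of AF Burden categories 1-4 (sum to 1).
#' @param prevalence named numeric vector of comorbidity prevalences
#'   (`hypertension`, `heart_failure`, `diabetes`, `renal_failure`,
#'   `myocardial_infarction`, `stroke`).
#' @param lvef_mean,lvef_sd left ventricular ejection fraction distribution.
#' @param paroxysmal_p probability of paroxysmal (vs persistent) AF.
#' @param ehra_probs probabilities of EHRA classes 1-4.
#' @param lavmax_mean,lavmax_sd log-normal moments (natural scale) of the
#'   maximum LA volume in ml.
#' @param coef_total,coef_active,coef_passive named coefficient vectors of
#'   the generative linear models (names: `intercept` plus covariate
#'   columns).
#' @param adj_r2 named vector of target adjusted R-squared values used to
#'   calibrate residual SDs.
#' @param clip_range emptying fractions are clipped to this range (percent).
#' @param total_model `"derived"` (default): total emptying fraction is
#'   derived from active and passive through the multiplicative identity;
#'   `"direct"`: generated from `coef_total` with its own residual.
#' @param pilot_n size of the pilot covariate draw used for residual-SD
#'   calibration.
#' @return An object of class `la_cohort_config`.
#' @export
cohort_config <- function(n_patients = 102L, seed = NULL,
                          age_mean = 60.8, age_sd = 8.9,
                          female_p = 18 / 102,
                          bmi_mean = 26.8, bmi_sd = 4.0,
                          bsa_mean = 2.02, bsa_sd = 0.21,
                          height_mean = 172, height_sd = 9,
                          afbs_probs = c(8, 65, 23, 5) / 101,
                          prevalence = c(hypertension = 55 / 102,
                                         heart_failure = 7 / 102,
                                         diabetes = 7 / 102,
                                         renal_failure = 8 / 102,
                                         myocardial_infarction = 3 / 102,
                                         stroke = 7 / 102),
                          lvef_mean = 57.4, lvef_sd = 8.0,
                          paroxysmal_p = 73 / 102,
                          ehra_probs = c(8, 57, 30, 1) / 96,
                          lavmax_mean = 102.5, lavmax_sd = 34.2,
                          coef_total = c(intercept = 75.98, age = -0.49,
                                         male_sex = 3.79, bmi = -0.01,
                                         heart_failure = -14.23,
                                         hypertension = -5.51),
                          coef_active = c(intercept = 61.82, age = -0.32,
                                          male_sex = 2.80, bmi = 0.02,
                                          afbs = -4.20,
                                          heart_failure = -12.12),
                          coef_passive = c(intercept = 18.10, age = -0.27,
                                           male_sex = 2.28, bmi = 0.05,
                                           lvef = 0.29),
                          adj_r2 = c(total = 0.32, active = 0.22,
                                     passive = 0.14),
                          clip_range = c(1, 95),
                          total_model = c("derived", "direct"),
                          pilot_n = 20000L) {
  total_model <- match.arg(total_model)
  n_patients <- as.integer(n_patients)
  if (n_patients < 10L) stop("`n_patients` must be >= 10", call. = FALSE)
  for (p in list(afbs_probs, ehra_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("category probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, seed = seed,
         age_mean = age_mean, age_sd = age_sd, female_p = female_p,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         bsa_mean = bsa_mean, bsa_sd = bsa_sd,
         height_mean = height_mean, height_sd = height_sd,
         afbs_probs = afbs_probs, prevalence = prevalence,
         lvef_mean = lvef_mean, lvef_sd = lvef_sd,
         paroxysmal_p = paroxysmal_p, ehra_probs = ehra_probs,
         lavmax_mean = lavmax_mean, lavmax_sd = lavmax_sd,
         coef_total = coef_total, coef_active = coef_active,
         coef_passive = coef_passive, adj_r2 = adj_r2,
         clip_range = clip_range, total_model = total_model,
         pilot_n = as.integer(pilot_n)),
    class = "la_cohort_config"
  )
}

# enumeration of AF-Burden component combinations, tagged by category code
afbs_combos <- function() {
  grid <- expand.grid(
    episode_frequency = c("lt4_per_year", "monthly", "weekly",
                          "ge2_per_week", "daily"),
    episode_duration = c("minutes", "hours", "most_of_day", "all_day"),
    n_cardioversions = 0:5,
    stringsAsFactors = FALSE
  )
  grid$category_code <- afbs(grid$episode_frequency, grid$episode_duration,
                             grid$n_cardioversions)$category_code
  grid
}

draw_covariates <- function(config, n) {
  sex <- ifelse(runif(n) < config$female_p, "female", "male")
  bsa <- pmax(rnorm(n, config$bsa_mean, config$bsa_sd), 1.2)
  height <- pmax(rnorm(n, config$height_mean, config$height_sd), 140)
  weight <- 3600 * bsa^2 / height # back-solved so Mosteller reproduces bsa
  afbs_code <- sample.int(4L, n, replace = TRUE, prob = config$afbs_probs)
  combos <- afbs_combos()
  comp_idx <- vapply(afbs_code, function(code) {
    pool <- which(combos$category_code == code)
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  df <- data.frame(
    patient_id = sprintf("SYN%04d", seq_len(n)),
    age = pmax(rnorm(n, config$age_mean, config$age_sd), 18),
    sex = sex,
    male_sex = as.integer(sex == "male"),
    height = height, weight = weight, bsa = bsa,
    bmi = pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15),
    afbs = afbs_code,
    episode_frequency = combos$episode_frequency[comp_idx],
    episode_duration = combos$episode_duration[comp_idx],
    n_cardioversions = combos$n_cardioversions[comp_idx],
    hypertension = runif(n) < config$prevalence[["hypertension"]],
    heart_failure = runif(n) < config$prevalence[["heart_failure"]],
    diabetes = runif(n) < config$prevalence[["diabetes"]],
    renal_failure = runif(n) < config$prevalence[["renal_failure"]],
    myocardial_infarction = runif(n) < config$prevalence[["myocardial_infarction"]],
    stroke = runif(n) < config$prevalence[["stroke"]],
    lvef = pmin(pmax(rnorm(n, config$lvef_mean, config$lvef_sd), 15), 80),
    af_type = ifelse(runif(n) < config$paroxysmal_p, "paroxysmal", "persistent"),
    ehra = sample.int(4L, n, replace = TRUE, prob = config$ehra_probs),
    stringsAsFactors = FALSE
  )
  df
}

# linear predictor of a named coefficient vector over data.frame columns;
# logical columns enter as 0/1
linear_predictor <- function(coefs, df) {
  lp <- rep(coefs[["intercept"]], nrow(df))
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% names(df)) {
      stop("coefficient refers to unknown covariate: ", nm, call. = FALSE)
    }
    lp <- lp + coefs[[nm]] * as.numeric(df[[nm]])
  }
  lp
}

# residual SD giving a target R2 for a linear model with predictor variance
# var_lp: R2 = var_lp / (var_lp + sigma^2) => sigma^2 = var_lp (1 - R2) / R2
residual_sd_for_r2 <- function(var_lp, r2) sqrt(var_lp * (1 - r2) / r2)

#' Simulate a cohort table with known generative coefficients
#'
#' Draws patient covariates from the configured distributions, generates
#' active and passive emptying fractions from their generative linear
#' models plus Gaussian residuals, and derives the total emptying fraction
#' through the multiplicative identity `(1-T) = (1-A)(1-P)` (or, with
#' `total_model = "direct"`, from its own coefficient set). Residual SDs
#' are calibrated on a pilot covariate draw so the fitted models attain the
#' configured adjusted R-squared: `sigma^2 = var(lp) * (1 - R2) / R2` with
#' `var(lp)` the pilot variance of the linear predictor. Emptying fractions
#' are clipped to `clip_range` and clip events counted. Fiducial volumes
#' are back-solved from the emptying fractions given a log-normal maximum
#' volume, and indexed volumes computed from the drawn BSA.
#'
#' @param config an [cohort_config()].
#' @return A list with `table` (the cohort data.frame, one row per patient,
#'   including covariates, AF classification scores, volumes, indexed
#'   volumes and emptying fractions) and `truth` (generator record: the
#'   coefficient sets, calibrated residual SDs and clip-event count).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 100, seed = 1))
#' head(cohort$table)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "la_cohort_config"))
  with_seed(config$seed, {
    pilot <- draw_covariates(config, config$pilot_n)
    sd_active <- residual_sd_for_r2(
      var(linear_predictor(config$coef_active, pilot)), config$adj_r2[["active"]])
    sd_passive <- residual_sd_for_r2(
      var(linear_predictor(config$coef_passive, pilot)), config$adj_r2[["passive"]])
    sd_total <- residual_sd_for_r2(
      var(linear_predictor(config$coef_total, pilot)), config$adj_r2[["total"]])

    n <- config$n_patients
    df <- draw_covariates(config, n)
    clip <- function(x) pmin(pmax(x, config$clip_range[1]), config$clip_range[2])
    raw_active <- linear_predictor(config$coef_active, df) + rnorm(n, sd = sd_active)
    raw_passive <- linear_predictor(config$coef_passive, df) + rnorm(n, sd = sd_passive)
    df$laef_active <- clip(raw_active)
    df$laef_passive <- clip(raw_passive)
    if (config$total_model == "direct") {
      raw_total <- linear_predictor(config$coef_total, df) + rnorm(n, sd = sd_total)
      df$laef_total <- clip(raw_total)
    } else {
      raw_total <- 100 * (1 - (1 - df$laef_active / 100) * (1 - df$laef_passive / 100))
      df$laef_total <- clip(raw_total)
    }
    clip_events <- sum(raw_active != df$laef_active) +
      sum(raw_passive != df$laef_passive) + sum(raw_total != df$laef_total)

    # back-solve fiducial volumes from the emptying fractions
    cv <- config$lavmax_sd / config$lavmax_mean
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(config$lavmax_mean) - sdlog^2 / 2
    df$v_max <- rlnorm(n, meanlog, sdlog)
    df$v_preA <- df$v_max * (1 - df$laef_passive / 100)
    if (config$total_model == "direct") {
      df$v_min <- pmin(df$v_max * (1 - df$laef_total / 100), df$v_preA)
    } else {
      df$v_min <- df$v_preA * (1 - df$laef_active / 100)
    }
    df$v_min2 <- df$v_preA - runif(n, 0.10, 0.25) * (df$v_preA - df$v_min)
    for (vv in c("v_max", "v_min", "v_preA", "v_min2")) {
      df[[paste0("lavi_", sub("v_", "", vv))]] <- df[[vv]] / df$bsa
    }
    df$mode <- "sinus_complete"
    df <- score_cohort(df)
    list(
      table = df,
      truth = list(
        coef_total = config$coef_total,
        coef_active = config$coef_active,
        coef_passive = config$coef_passive,
        residual_sd = c(total = sd_total, active = sd_active,
                        passive = sd_passive),
        total_model = config$total_model,
        clip_events = clip_events
      )
    )
  })
}
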