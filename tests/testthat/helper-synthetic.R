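# Shared fixture builders. Everything is generated in code at test time.

# A mixed batch of curves with known labels: 10 sinus, 3 AF-mode,
# 2 extrasystole-corrupted.
make_curve_batch <- function() {
  curves <- list()
  for (i in 1:10) {
    id <- sprintf("P%02d", i)
    p <- curve_params(v_max = 90 + 2 * i, v_min = 45 + i, v_preA = 72 + i,
                      v_min2 = 68 + i, noise_sd = 1, patient_id = id)
    curves[[id]] <- simulate_curve(p, seed = 10 + i)$curve
  }
  for (i in 11:13) {
    id <- sprintf("P%02d", i)
    curves[[id]] <- simulate_af_curve(v_max = 95 + i, v_min = 60 + i,
                                      noise_sd = 1, seed = 10 + i,
                                      patient_id = id)$curve
  }
  for (i in 14:15) {
    id <- sprintf("P%02d", i)
    base <- simulate_curve(curve_params(patient_id = id))$curve
    curves[[id]] <- corrupt_with_extrasystoles(base, 0.2, 3, seed = 10 + i)
  }
  curves
}

# Minimal clinical table matching the batch above.
make_clinical_table <- function(ids, seed = 99) {
  n <- length(ids)
  withr::with_seed(seed, data.frame(
    patient_id = ids,
    age = round(runif(n, 45, 78)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.2, 0.8)),
    height = round(runif(n, 158, 190)),
    weight = round(runif(n, 60, 100)),
    episode_frequency = sample(c("lt4_per_year", "monthly", "weekly"), n, TRUE),
    episode_duration = sample(c("minutes", "hours"), n, TRUE),
    n_cardioversions = sample(0:3, n, TRUE),
    af_type = sample(c("paroxysmal", "persistent"), n, TRUE),
    ehra = sample(1:3, n, TRUE),
    heart_failure = runif(n) < 0.15,
    hypertension = runif(n) < 0.5,
    diabetes = runif(n) < 0.1,
    stroke = runif(n) < 0.1,
    renal_failure = runif(n) < 0.1,
    myocardial_infarction = runif(n) < 0.05,
    lvef = round(runif(n, 45, 70)),
    stringsAsFactors = FALSE
  ))
}

# Write the batch + clinical table to a directory, return the paths.
make_pipeline_inputs <- function(dir) {
  curves <- make_curve_batch()
  curves_csv <- file.path(dir, "curves.csv")
  clinical_csv <- file.path(dir, "clinical.csv")
  write_curves_csv(curves, curves_csv)
  write.csv(make_clinical_table(names(curves)), clinical_csv, row.names = FALSE)
  list(curves_csv = curves_csv, clinical_csv = clinical_csv, curves = curves)
}

# Small random regression design for OLS oracle checks.
make_small_design <- function(seed, n = NULL, p = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(10:40, 1)
    if (is.null(p)) p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p + 1, sd = 2)
    y <- beta[1] + X %*% beta[-1] + rnorm(n)
    df <- as.data.frame(X)
    names(df) <- paste0("x", seq_len(p))
    df$y <- as.numeric(y)
    df
  })
}

# Independent OLS oracle: closed-form normal equations, never lm().
ols_oracle <- function(df, outcome, predictors) {
  X <- cbind(1, as.matrix(df[predictors]))
  y <- df[[outcome]]
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

expect_cyclic_close <- function(idx, truth, n, tol = 1L) {
  d <- abs(idx - truth) %% n
  expect_true(all(pmin(d, n - d) <= tol))
}
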