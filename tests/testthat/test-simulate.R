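test_that("curve parameters are validated", {
  expect_error(curve_params(v_min = 90, v_min2 = 80), "v_min <= v_min2")
  expect_error(curve_params(phase_fractions = c(0.5, 0.4, 0.8)), "increasing")
  expect_error(curve_params(phase_fractions = c(0.2, 0.25, 0.9)),
               "too close")
  expect_error(curve_params(n_frames = 3), ">= 5")
  expect_error(curve_params(noise_sd = -1), ">= 0")
})

test_that("the noiseless curve attains its parameters exactly at the phase frames", {
  p <- curve_params() # (100, 50, 80, 75) at (0.36, 0.64, 0.80), 25 frames
  v <- simulate_curve(p)$curve$volumes_ml
  expect_equal(v[9 + 1], 100)  # maximum at frame 9
  expect_equal(v[16 + 1], 75)  # diastasis minimum at frame 16
  expect_equal(v[20 + 1], 80)  # pre-contraction bump at frame 20
  expect_equal(v[0 + 1], 50)   # cycle starts (and wraps) at the minimum
  expect_equal(max(v), 100)
  expect_equal(min(v), 50)
  # the local structure holds: frame 16 is the lowest point between 9 and 20
  expect_equal(which.min(v[10:21]) + 9, 16 + 1)
})

test_that("curve generation is seed-deterministic", {
  p <- curve_params(noise_sd = 2)
  c1 <- simulate_curve(p, seed = 123)$curve
  c2 <- simulate_curve(p, seed = 123)$curve
  expect_identical(c1$volumes_ml, c2$volumes_ml)
  c3 <- simulate_curve(p, seed = 124)$curve
  expect_false(identical(c1$volumes_ml, c3$volumes_ml))

  a1 <- simulate_af_curve(noise_sd = 2, seed = 5)$curve
  a2 <- simulate_af_curve(noise_sd = 2, seed = 5)$curve
  expect_identical(a1$volumes_ml, a2$volumes_ml)

  base <- simulate_curve(curve_params())$curve
  x1 <- corrupt_with_extrasystoles(base, 0.2, 2, seed = 9)
  x2 <- corrupt_with_extrasystoles(base, 0.2, 2, seed = 9)
  expect_identical(x1$volumes_ml, x2$volumes_ml)
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_curve(curve_params(noise_sd = 2), seed = 99))
  invisible(simulate_cohort(cohort_config(n_patients = 20, seed = 7,
                                          pilot_n = 500)))
  expect_identical(.Random.seed, before)
})

test_that("AF-mode curves fall monotonically after the maximum", {
  sim <- simulate_af_curve(v_max = 100, v_min = 50, t_max = 0.36)
  v <- sim$curve$volumes_ml
  i1 <- sim$truth$i_max + 1
  expect_true(all(diff(v[i1:length(v)]) <= 1e-12))
  expect_true(all(diff(v[1:i1]) >= -1e-12))
})

test_that("extrasystole corruption is a no-op at amplitude zero", {
  base <- simulate_curve(curve_params())$curve
  expect_identical(corrupt_with_extrasystoles(base, 0, 3, seed = 1)$volumes_ml,
                   base$volumes_ml)
  changed <- corrupt_with_extrasystoles(base, 0.15, 2, seed = 1)
  expect_false(identical(changed$volumes_ml, base$volumes_ml))
  expect_true(all(changed$volumes_ml >= 0))
})

test_that("generator and detector form an exact round trip without noise", {
  for (s in 1:5) {
    p <- withr::with_seed(s, curve_params(
      v_max = runif(1, 90, 130), v_min = runif(1, 40, 60),
      v_preA = runif(1, 75, 88), v_min2 = runif(1, 65, 74)
    ))
    sim <- simulate_curve(p)
    f <- detect_fiducials(sim$curve)
    expect_identical(f$mode, "sinus_complete")
    expect_equal(c(f$v_max, f$v_min, f$v_preA, f$v_min2),
                 c(p$v_max, p$v_min, p$v_preA, p$v_min2), tolerance = 1e-8)
  }
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_patients = 5), ">= 10")
  expect_error(cohort_config(afbs_probs = c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
  expect_error(cohort_config(prevalence = c(hypertension = 1.2,
                                            heart_failure = 0.1,
                                            diabetes = 0.1,
                                            renal_failure = 0.1,
                                            myocardial_infarction = 0.1,
                                            stroke = 0.1)),
               "\\[0, 1\\]")
})

test_that("cohort simulation is reproducible and internally consistent", {
  cfg <- cohort_config(n_patients = 150, seed = 31, pilot_n = 2000)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$table, s2$table)

  tb <- s1$table
  expect_identical(anyDuplicated(tb$patient_id), 0L)
  # emptying fractions respect the clip range and the multiplicative identity
  expect_true(all(tb$laef_active >= 1 & tb$laef_active <= 95))
  unclipped <- abs(100 * (1 - (1 - tb$laef_active / 100) *
                            (1 - tb$laef_passive / 100)) - tb$laef_total) < 1e-9
  expect_gte(mean(unclipped), 0.95) # identity holds wherever nothing clipped
  # back-solved volumes are ordered and consistent with the fractions
  expect_true(all(tb$v_min <= tb$v_min2 + 1e-9 &
                    tb$v_min2 <= tb$v_preA + 1e-9 &
                    tb$v_preA <= tb$v_max + 1e-9))
  expect_equal(laef_total(tb$v_max, tb$v_min), tb$laef_total, tolerance = 1e-9)
  expect_equal(laef_active(tb$v_preA, tb$v_min), tb$laef_active,
               tolerance = 1e-9)
  # indexed volumes times BSA give back the absolute volumes
  expect_equal(tb$lavi_max * tb$bsa, tb$v_max, tolerance = 1e-9)
  # Mosteller on the drawn height/weight reproduces the drawn BSA
  expect_equal(bsa_mosteller(tb$height, tb$weight), tb$bsa, tolerance = 1e-9)
  # AFBS components always re-score to the drawn category
  expect_identical(afbs(tb$episode_frequency, tb$episode_duration,
                        tb$n_cardioversions)$category_code, tb$afbs)
})

test_that("cohort marginals converge to the configured distributions", {
  cfg <- cohort_config(n_patients = 50000, seed = 8, pilot_n = 1000)
  tb <- simulate_cohort(cfg)$table
  n <- nrow(tb)
  within_3se <- function(x, mean_target, sd_target) {
    abs(mean(x) - mean_target) <= 3 * sd_target / sqrt(n)
  }
  expect_true(within_3se(tb$age, cfg$age_mean, cfg$age_sd))
  expect_true(within_3se(tb$bmi, cfg$bmi_mean, cfg$bmi_sd))
  expect_true(within_3se(tb$bsa, cfg$bsa_mean, cfg$bsa_sd))
  p <- cfg$female_p
  expect_true(abs(mean(tb$sex == "female") - p) <= 3 * sqrt(p * (1 - p) / n))
  for (k in 1:4) {
    pk <- cfg$afbs_probs[k]
    expect_true(abs(mean(tb$afbs == k) - pk) <= 3 * sqrt(pk * (1 - pk) / n))
  }
  expect_true(within_3se(tb$v_max, cfg$lavmax_mean,
                         cfg$lavmax_sd * 1.1)) # log-normal: slightly wider
})

test_that("zero residual variance collapses the outcome onto the linear model", {
  cfg <- cohort_config(n_patients = 50, seed = 4, pilot_n = 500,
                       adj_r2 = c(total = 1, active = 1, passive = 1))
  sim <- simulate_cohort(cfg)
  tb <- sim$table
  expect_equal(unname(sim$truth$residual_sd), rep(0, 3))
  lp <- cfg$coef_active[["intercept"]] +
    cfg$coef_active[["age"]] * tb$age +
    cfg$coef_active[["male_sex"]] * tb$male_sex +
    cfg$coef_active[["bmi"]] * tb$bmi +
    cfg$coef_active[["afbs"]] * tb$afbs +
    cfg$coef_active[["heart_failure"]] * as.numeric(tb$heart_failure)
  expect_equal(tb$laef_active, pmin(pmax(lp, 1), 95), tolerance = 1e-12)
})

test_that("residual calibration hits the target adjusted R-squared", {
  sim <- simulate_cohort(cohort_config(n_patients = 20000, seed = 12,
                                       pilot_n = 20000))
  m <- fit_mlrm_stepwise(
    sim$table, "laef_active", candidates = c("afbs", "heart_failure"),
    forced = c("age", "male_sex", "bmi")
  )
  expect_equal(m$adjusted_r2, 0.22, tolerance = 0.03)
})
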