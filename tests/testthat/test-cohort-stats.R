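test_that("identical groups give p = 1 and independence gives Fisher p = 1", {
  d <- data.frame(g = rep(c("a", "b"), each = 10), y = rep(1:10, 2))
  res <- compare_groups(d, "g", "y")$y
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  d2 <- data.frame(g = rep(c("a", "b"), each = 10),
                   f = rep(rep(c("x", "y"), each = 5), 2))
  res2 <- compare_groups(d2, "g", "f")$f
  expect_identical(res2$test, "fisher_exact")
  expect_equal(res2$p_value, 1)
})

test_that("test routing follows per-group Shapiro normality", {
  set.seed(21)
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 40),
    normal = rnorm(120, rep(c(0, 1, 2), each = 40)),
    skewed = rlnorm(120, rep(c(0, 0.5, 1), each = 40), 1)
  )
  res <- compare_groups(d, "g", c("normal", "skewed"))
  # independent routing oracle: rerun Shapiro per group at alpha = 0.05
  route <- function(v) {
    all(vapply(split(d[[v]], d$g),
               function(x) shapiro.test(x)$p.value >= 0.05, logical(1)))
  }
  expect_identical(res$normal$test, if (route("normal")) "anova" else "kruskal_wallis")
  expect_identical(res$skewed$test, if (route("skewed")) "anova" else "kruskal_wallis")
  # this draw is normal/skewed by construction
  expect_identical(res$normal$test, "anova")
  expect_identical(res$skewed$test, "kruskal_wallis")
  expect_identical(unique(res$normal$descriptives$style), "mean_sd")
  expect_identical(unique(res$skewed$descriptives$style), "median_iqr")
  # descriptives match direct computation
  expect_equal(res$normal$descriptives$center,
               as.numeric(tapply(d$normal, d$g, mean)), tolerance = 1e-12)
  expect_equal(res$skewed$descriptives$spread,
               as.numeric(tapply(d$skewed, d$g, IQR)), tolerance = 1e-12)
  # two-group parametric route uses the t-test
  d2 <- d[d$g != "c", ]
  expect_identical(compare_groups(d2, "g", "normal")$normal$test, "t_test")
})

test_that("routing is deterministic and tiny groups force the rank route", {
  set.seed(5)
  d <- data.frame(g = c(rep("a", 20), rep("b", 2)), y = rnorm(22))
  expect_warning(res <- compare_groups(d, "g", "y"), "n < 3")
  expect_identical(res$y$test, "kruskal_wallis")
  r1 <- compare_groups(data.frame(g = rep(c("a", "b"), 25), y = rnorm(50)),
                       "g", "y")
  # same data, same routing and p
  d3 <- data.frame(g = rep(c("a", "b"), 25), y = rnorm(50))
  expect_identical(compare_groups(d3, "g", "y")$y$p_value,
                   compare_groups(d3, "g", "y")$y$p_value)
})

test_that("post-hoc pairs appear only for significant >2-group tests, Bonferroni-corrected", {
  set.seed(8)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 30),
                  y = rnorm(90, rep(c(0, 0, 3), each = 30)))
  res <- compare_groups(d, "g", "y")$y
  expect_false(is.null(res$posthoc))
  expect_true(all(res$posthoc$p_corrected <= 1))
  if (res$test == "anova") {
    raw <- pairwise.t.test(d$y, d$g, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    corr <- pairwise.t.test(d$y, d$g, p.adjust.method = "bonferroni",
                            pool.sd = TRUE)$p.value
    expect_equal(corr, pmin(raw * 3, 1)) # m = 3 pairwise tests
    expect_true(all(corr >= raw, na.rm = TRUE))
  }
  # a null 3-group comparison carries no post-hoc block
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 30), y = rnorm(90))
  res0 <- compare_groups(d0, "g", "y")$y
  if (res0$p_value >= 0.05) expect_null(res0$posthoc)
})

test_that("grouped emptying-fraction differences are detected at published effect sizes", {
  # four AF-burden groups drawn at the published active-LAEF means/SDs/sizes
  means <- c(44.0, 36.2, 31.7, 20.8)
  sds <- c(11.0, 11.0, 11.8, 17.5)
  ns <- c(8, 65, 23, 5)
  set.seed(42)
  hits <- 0
  hits_oracle <- 0
  for (r in 1:100) {
    y <- unlist(lapply(1:4, function(k) rnorm(ns[k], means[k], sds[k])))
    g <- factor(rep(paste0("afbs", 1:4), ns))
    d <- data.frame(g = g, y = y)
    res <- suppressWarnings(compare_groups(d, "g", "y"))$y
    # independent reference: same Shapiro-routed family, called directly
    normal <- all(vapply(split(y, g), function(x)
      shapiro.test(x)$p.value >= 0.05, logical(1)))
    p_ref <- if (normal) {
      anova(aov(y ~ g))[["Pr(>F)"]][1]
    } else {
      kruskal.test(y, g)$p.value
    }
    expect_equal(res$p_value, p_ref, tolerance = 1e-12)
    if (res$p_value < 0.05) hits <- hits + 1
    if (p_ref < 0.05) hits_oracle <- hits_oracle + 1
  }
  expect_identical(hits, hits_oracle)
  # the reference computation puts the power at these group sizes near 86%
  expect_gte(hits, 80)
})

test_that("univariable OLS matches the closed-form normal equations", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x
  r <- suppressWarnings(fit_ulrm(d, "y", "x")) # exact fit: summary warns
  b <- r$terms[r$terms$term == "x", ]
  expect_equal(b$estimate, 2, tolerance = 1e-12)
  expect_equal(b$ci_high - b$ci_low, 0, tolerance = 1e-8)
  expect_lt(b$p, 1e-12)

  for (s in 1:50) {
    df <- make_small_design(s)
    r2 <- fit_ulrm(df, "y", "x1")
    oracle <- ols_oracle(df, "y", "x1")
    expect_equal(r2$terms$estimate, unname(oracle), tolerance = 1e-8)
  }
  expect_error(fit_ulrm(data.frame(x = rep(1, 10), y = rnorm(10)), "y", "x"),
               "degenerate")
})

test_that("an unrelated predictor is usually not significant", {
  set.seed(31)
  base_y <- rnorm(1000)
  base_x <- rnorm(1000)
  hits <- 0
  for (s in 1:100) {
    d <- data.frame(y = base_y, x = sample(base_x)) # permuted: no relation
    r <- fit_ulrm(d, "y", "x")
    if (r$terms$p[r$terms$term == "x"] > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("forward selection keeps forced covariates and matches a brute-force oracle", {
  noise <- withr::with_seed(1, {
    n <- 120
    d <- data.frame(age = rnorm(n, 60, 9), male_sex = rbinom(n, 1, 0.8),
                    bmi = rnorm(n, 27, 4))
    for (j in 1:4) d[[paste0("z", j)]] <- rnorm(n)
    d$y <- rnorm(n) # outcome unrelated to anything
    d
  })
  m <- fit_mlrm_stepwise(noise, "y", paste0("z", 1:4))
  expect_length(m$selected, 0)
  expect_true(all(c("age", "male_sex", "bmi") %in%
                    sub("TRUE$", "", m$terms$term[-1])))
  expect_identical(sort(m$excluded_terms$term), paste0("z", 1:4))
  expect_true(all(m$excluded_terms$p_at_exclusion >= 0.1))

  # brute-force forward-selection oracle on random designs
  oracle_forward <- function(d, outcome, cands, forced, entry_p = 0.1) {
    selected <- character(0)
    repeat {
      rem <- setdiff(cands, selected)
      if (!length(rem)) break
      ps <- vapply(rem, function(cn) {
        f1 <- lm(reformulate(c(forced, selected, cn), response = outcome), d)
        f0 <- lm(reformulate(c(forced, selected), response = outcome), d)
        anova(f0, f1)[["Pr(>F)"]][2] # partial F-test of the added term
      }, numeric(1))
      ord <- order(ps, rem)
      if (ps[ord[1]] >= entry_p) break
      selected <- c(selected, rem[ord[1]])
    }
    selected
  }
  for (s in 1:20) {
    d <- withr::with_seed(700 + s, {
      n <- 80
      d <- data.frame(age = rnorm(n, 60, 9), male_sex = rbinom(n, 1, 0.8),
                      bmi = rnorm(n, 27, 4))
      for (j in 1:4) d[[paste0("c", j)]] <- rnorm(n)
      d$y <- 0.2 * d$age + 1.5 * d$c1 +
        sample(c(0, 0.8), 1) * d$c2 + rnorm(n, sd = 2)
      d
    })
    got <- fit_mlrm_stepwise(d, "y", paste0("c", 1:4))$selected
    want <- oracle_forward(d, "y", paste0("c", 1:4),
                           c("age", "male_sex", "bmi"))
    expect_identical(got, want)
  }
})

test_that("collinear candidates are dropped with a warning", {
  set.seed(9)
  n <- 60
  d <- data.frame(age = rnorm(n, 60, 9), male_sex = rbinom(n, 1, 0.8),
                  bmi = rnorm(n, 27, 4))
  d$dup <- 2 * d$age - 1 # aliased with a forced covariate
  d$good <- rnorm(n)
  d$y <- d$age + 3 * d$good + rnorm(n)
  expect_warning(m <- fit_mlrm_stepwise(d, "y", c("dup", "good")),
                 "collinear")
  expect_identical(m$selected, "good")
})

test_that("the published active-LAEF model is recovered from a large synthetic cohort", {
  sim <- simulate_cohort(cohort_config(n_patients = 5000, seed = 2024))
  m <- fit_mlrm_stepwise(
    sim$table, "laef_active",
    candidates = c("afbs", "heart_failure", "hypertension", "diabetes",
                   "renal_failure", "lvef", "cha2ds2vasc", "ehra"),
    forced = c("age", "male_sex", "bmi")
  )
  expect_true(all(c("afbs", "heart_failure") %in% m$selected))
  tt <- m$terms
  b_afbs <- tt[tt$term == "afbs", ]
  b_hf <- tt[grepl("^heart_failure", tt$term), ]
  expect_lt(b_afbs$estimate, 0)
  expect_lt(b_hf$estimate, 0)
  # each generator coefficient inside the fit's own 95% CI
  expect_true(b_afbs$ci_low <= -4.20 && -4.20 <= b_afbs$ci_high)
  expect_true(b_hf$ci_low <= -12.12 && -12.12 <= b_hf$ci_high)
  # confidence intervals bracket their estimates
  expect_true(all(tt$ci_low <= tt$estimate & tt$estimate <= tt$ci_high))
})
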