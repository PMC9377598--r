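#' Normality-routed group comparisons
#'
#' For each numeric variable, per-group normality is assessed with the
#' Shapiro-Wilk test (alpha = 0.05). If every group is compatible with
#' normality the parametric route is taken (two groups: pooled t-test; more
#' than two: one-way ANOVA) and descriptives are reported as mean +/- SD;
#' otherwise the Kruskal-Wallis test is used (which for two groups is the
#' rank test of the same family) and descriptives are median +/- IQR. With
#' more than two groups and a significant overall test, pairwise post-hoc
#' comparisons are run (pairwise t-tests with pooled SD after ANOVA,
#' pairwise Wilcoxon rank-sum tests after Kruskal-Wallis), Bonferroni
#' corrected. Factor/character/logical variables are compared with Fisher's
#' exact test on the contingency table.
#'
#' Groups with fewer than 3 observations cannot be tested for normality: the
#' variable is routed non-parametrically with a warning.
#'
#' @param data data.frame with one row per patient.
#' @param grouping name of the grouping column (>= 2 non-empty levels).
#' @param variables character vector of column names to compare.
#' @param alpha significance level for the Shapiro gate and for triggering
#'   post-hoc tests (default 0.05).
#' @return A named list of `la_group_comparison` objects, one per variable,
#'   each with fields `variable`, `grouping`, `test` (`"t_test"`, `"anova"`,
#'   `"kruskal_wallis"` or `"fisher_exact"`), `p_value`, `normal` (logical or
#'   NA), `descriptives` (data.frame: group, n, center, spread, style) and
#'   `posthoc` (data.frame of Bonferroni-corrected pairwise p-values, or
#'   NULL).
#' @export
compare_groups <- function(data, grouping, variables, alpha = 0.05) {
  stopifnot(is.data.frame(data), grouping %in% names(data))
  g_all <- data[[grouping]]
  if (!is.factor(g_all)) g_all <- factor(g_all)
  g_all <- droplevels(g_all)
  if (nlevels(g_all) < 2) {
    stop("`grouping` must have at least 2 non-empty levels", call. = FALSE)
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(variables, function(v) {
    compare_one(data[[v]], g_all, v, grouping, alpha)
  })
  names(out) <- variables
  out
}

compare_one <- function(x, g, variable, grouping, alpha) {
  if (is.numeric(x)) {
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; gg <- droplevels(g[keep])
    groups <- split(x, gg)
    ns <- vapply(groups, length, integer(1))
    small <- ns < 3
    if (any(small)) {
      warning(sprintf(
        "%s: group(s) %s have n < 3; normality not assessable, non-parametric route forced",
        variable, paste(names(groups)[small], collapse = ", ")
      ), call. = FALSE)
      normal <- NA
    } else {
      shapiro_p <- vapply(groups, function(gr) {
        if (length(unique(gr)) == 1) return(0) # degenerate: not normal
        shapiro.test(gr)$p.value
      }, numeric(1))
      normal <- all(shapiro_p >= alpha)
    }
    parametric <- isTRUE(normal)
    if (parametric) {
      if (nlevels(gg) == 2) {
        test <- "t_test"
        p <- t.test(x ~ gg, var.equal = TRUE)$p.value
      } else {
        test <- "anova"
        p <- anova(aov(x ~ gg))[["Pr(>F)"]][1]
      }
    } else {
      test <- "kruskal_wallis"
      p <- kruskal.test(x, gg)$p.value
    }
    desc <- data.frame(
      group = names(groups), n = ns,
      center = vapply(groups, if (parametric) mean else median, numeric(1)),
      spread = vapply(groups, if (parametric) sd else IQR, numeric(1)),
      style = if (parametric) "mean_sd" else "median_iqr",
      stringsAsFactors = FALSE, row.names = NULL
    )
    posthoc <- NULL
    if (nlevels(gg) > 2 && is.finite(p) && p < alpha) {
      ph <- if (parametric) {
        pairwise.t.test(x, gg, p.adjust.method = "bonferroni", pool.sd = TRUE)
      } else {
        suppressWarnings(
          pairwise.wilcox.test(x, gg, p.adjust.method = "bonferroni")
        )
      }
      m <- ph$p.value
      posthoc <- data.frame(
        group1 = rep(rownames(m), ncol(m)),
        group2 = rep(colnames(m), each = nrow(m)),
        p_corrected = as.vector(m),
        stringsAsFactors = FALSE
      )
      posthoc <- posthoc[!is.na(posthoc$p_corrected), , drop = FALSE]
      row.names(posthoc) <- NULL
    }
    result <- list(variable = variable, grouping = grouping, test = test,
                   p_value = p, normal = normal, descriptives = desc,
                   posthoc = posthoc)
  } else {
    keep <- !is.na(x) & !is.na(g)
    tab <- table(x[keep], droplevels(g[keep]))
    p <- fisher.test(tab)$p.value
    result <- list(variable = variable, grouping = grouping,
                   test = "fisher_exact", p_value = p, normal = NA,
                   descriptives = as.data.frame(tab, stringsAsFactors = FALSE),
                   posthoc = NULL)
  }
  structure(result, class = "la_group_comparison")
}

#' @export
print.la_group_comparison <- function(x, ...) {
  cat(sprintf("<la_group_comparison> %s by %s: %s, p = %.4g\n",
              x$variable, x$grouping, x$test, x$p_value))
  print(x$descriptives, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Univariable linear regression
#'
#' Ordinary least squares of `outcome` on a single predictor with
#' intercept; reports the coefficient, its 95% confidence interval and
#' p-value, plus the adjusted R-squared.
#'
#' @param data data.frame.
#' @param outcome,predictor column names.
#' @return An `la_regression` object; see [fit_mlrm_stepwise()].
#' @export
fit_ulrm <- function(data, outcome, predictor) {
  stopifnot(outcome %in% names(data), predictor %in% names(data))
  d <- data[complete.cases(data[c(outcome, predictor)]), c(outcome, predictor)]
  if (nrow(d) < 3) stop("need at least 3 complete cases", call. = FALSE)
  x <- d[[predictor]]
  if (length(unique(x[!is.na(x)])) < 2) {
    stop("constant predictor (degenerate design): ", predictor, call. = FALSE)
  }
  fit <- lm(reformulate(sprintf("`%s`", predictor), response = sprintf("`%s`", outcome)),
            data = d)
  new_regression(fit, outcome, excluded = data.frame(
    term = character(0), p_at_exclusion = numeric(0), stringsAsFactors = FALSE
  ))
}

new_regression <- function(fit, outcome, excluded) {
  cf <- coef(summary(fit))
  ci <- confint(fit)
  terms <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    ci_low = ci[rownames(cf), 1],
    ci_high = ci[rownames(cf), 2],
    p = cf[, "Pr(>|t|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(outcome = outcome, terms = terms,
         adjusted_r2 = summary(fit)$adj.r.squared,
         excluded_terms = excluded, fit = fit),
    class = "la_regression"
  )
}

#' @export
print.la_regression <- function(x, ...) {
  cat(sprintf("<la_regression> outcome %s, adjusted R2 = %.3f\n",
              x$outcome, x$adjusted_r2))
  tt <- x$terms
  tt$estimate <- round(tt$estimate, 3)
  tt$ci_low <- round(tt$ci_low, 3)
  tt$ci_high <- round(tt$ci_high, 3)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  if (nrow(x$excluded_terms)) {
    cat("excluded candidates (p at last evaluation):\n")
    print(x$excluded_terms, row.names = FALSE)
  }
  invisible(x)
}

#' Forward-stepwise multivariable linear regression with forced covariates
#'
#' Starts from a model containing the forced covariates (by default age,
#' sex and BMI, which are never removed), then repeatedly evaluates every
#' remaining candidate alongside the current model and adds the one with
#' the smallest entry p-value below `entry_p` (default 0.1). Entry p-values
#' are single-term F-tests (`drop1`), which for one-degree-of-freedom terms
#' equal the Wald t-test; ties are broken by smaller p, then alphabetical
#' term name. Selection stops when no candidate qualifies. Candidates that
#' are collinear with the current model (aliased coefficients) are dropped
#' with a warning. Complete cases across outcome, forced covariates and all
#' candidates are used throughout so every step sees the same rows.
#'
#' @param data data.frame.
#' @param outcome name of the outcome column.
#' @param candidates character vector of candidate predictor columns
#'   (disjoint from `forced`).
#' @param forced character vector of forced covariates.
#' @param entry_p entry threshold for the forward step (default 0.1).
#' @return An object of class `la_regression` with fields `outcome`,
#'   `terms` (data.frame: term, estimate, ci_low, ci_high, p),
#'   `adjusted_r2`, `excluded_terms` (data.frame: term, p_at_exclusion) and
#'   the underlying `fit`.
#' @export
fit_mlrm_stepwise <- function(data, outcome, candidates,
                              forced = c("age", "male_sex", "bmi"),
                              entry_p = 0.1) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (length(intersect(forced, candidates))) {
    stop("`candidates` must be disjoint from `forced`", call. = FALSE)
  }
  all_cols <- c(outcome, forced, candidates)
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[complete.cases(data[all_cols]), all_cols, drop = FALSE]
  if (nrow(d) < length(forced) + 2) {
    stop("not enough complete cases for the forced model", call. = FALSE)
  }
  bt <- function(v) sprintf("`%s`", v)
  selected <- character(0)
  remaining <- candidates
  last_p <- setNames(rep(NA_real_, length(candidates)), candidates)
  repeat {
    if (!length(remaining)) break
    entry <- vapply(remaining, function(cand) {
      f <- reformulate(bt(c(forced, selected, cand)), response = bt(outcome))
      fit <- lm(f, data = d)
      if (anyNA(coef(fit))) return(NA_real_)
      dr <- drop1(fit, scope = reformulate(bt(cand)), test = "F")
      dr[["Pr(>F)"]][2]
    }, numeric(1))
    collinear <- is.na(entry)
    if (any(collinear)) {
      warning("dropping collinear candidate(s): ",
              paste(remaining[collinear], collapse = ", "), call. = FALSE)
      remaining <- remaining[!collinear]
      entry <- entry[!collinear]
      if (!length(remaining)) break
    }
    last_p[remaining] <- entry
    ord <- order(entry, remaining) # ties: smaller p, then alphabetical
    best <- ord[1]
    if (entry[best] >= entry_p) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  final <- lm(reformulate(bt(c(forced, selected)), response = bt(outcome)),
              data = d)
  excluded <- data.frame(
    term = setdiff(candidates, selected),
    stringsAsFactors = FALSE
  )
  excluded$p_at_exclusion <- unname(last_p[excluded$term])
  res <- new_regression(final, outcome, excluded)
  res$forced <- forced
  res$selected <- selected
  res
}
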