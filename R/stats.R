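# Classical validation battery: 2x2 odds ratios, two-group univariate
# comparisons, and multivariable logistic regression with Wald intervals.

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` on the exposed/event layout `a` = group-1 events,
#' `b` = group-1 non-events, `c` = group-2 events, `d` = group-2
#' non-events.  When any cell is zero the Haldane-Anscombe correction
#' (+0.5 on all four cells) is applied; the log-normal (Woolf) interval
#' uses the same corrected cells.
#'
#' @param table length-4 numeric `c(a, b, c, d)` or a 2x2 matrix in
#'   row-major `(a, b / c, d)` layout.
#' @param ci_level confidence level (default 0.95).
#' @return named numeric `c(or, ci_low, ci_high)`.
#' @export
odds_ratio <- function(table, ci_level = 0.95) {
  x <- if (is.matrix(table)) as.numeric(t(table)) else as.numeric(table)
  stopifnot(length(x) == 4, all(x >= 0), sum(x) > 0)
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) {
    stop("all-zero margin in 2x2 table")
  }
  if (any(x == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm((1 + ci_level) / 2)
  c(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

# sample skewness (used by the t-vs-Wilcoxon screen)
.skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# Resolve a variable specification against the per-patient table:
# "attribute=value" indicators, bare intervention/outcome/trigger flag
# labels (read from the first call), or raw column names.
resolve_variable <- function(pt, spec) {
  if (grepl("=", spec, fixed = TRUE)) {
    parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
    attr_col <- switch(parts[1],
                       location = "first_location",
                       trigger = "first_triggers",
                       clinical_unit = "clinical_unit",
                       diagnosis_group = "diagnosis_group",
                       gender = "gender",
                       stop("unknown attribute in variable: ", spec))
    if (parts[1] == "trigger") {
      return(cell_has(pt$first_triggers, parts[2]))
    }
    return(pt[[attr_col]] == parts[2])
  }
  if (spec %in% met_vocab$interventions) {
    return(cell_has(pt$first_interventions, spec))
  }
  if (spec %in% met_vocab$outcome_flags) {
    return(cell_has(pt$first_outcome_flags, spec))
  }
  if (spec %in% met_vocab$triggers) {
    return(cell_has(pt$first_triggers, spec))
  }
  if (!spec %in% names(pt)) stop("unknown variable: ", spec)
  pt[[spec]]
}

#' Univariate two-group comparison battery
#'
#' One row per variable, with the test selected by a deterministic
#' policy: categorical variables get a chi-square test (Fisher's exact
#' test when any expected cell is below 5); continuous variables get a
#' Wilcoxon rank-sum test unless both groups look close enough to normal
#' (n >= 30 and |skewness| <= 1 in each), in which case a Welch t-test
#' is used.  No multiplicity adjustment is applied.
#'
#' @param cohort a [met_cohort()].
#' @param grouping logical vector over [patient_table()] rows, or a
#'   function of the patient table returning one; `TRUE` = group 1.
#'   `NA` rows are dropped.
#' @param variables character vector of variable specifications (see
#'   [resolve_variable()]): e.g. `"age_years"`, `"los_days"`,
#'   `"clinical_unit=heart_failure"`, `"ecg"`, `"multiple_met"`.
#' @return data frame of class `comparison_table` with columns
#'   `variable`, `group1_summary`, `group2_summary`, `test_used`,
#'   `p_value`.
#' @export
compare_groups <- function(cohort, grouping, variables) {
  pt <- patient_table(cohort)
  g <- if (is.function(grouping)) grouping(pt) else grouping
  stopifnot(length(g) == nrow(pt))
  keep <- !is.na(g)
  pt <- pt[keep, , drop = FALSE]
  g <- g[keep]
  if (!any(g) || !any(!g)) stop("empty group")
  rows <- lapply(variables, function(v) .compare_one(pt, g, v))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

.compare_one <- function(pt, g, spec) {
  x <- resolve_variable(pt, spec)
  n1 <- sum(g); n2 <- sum(!g)
  if (is.logical(x)) {
    a <- sum(x[g], na.rm = TRUE); b <- n1 - a
    cc <- sum(x[!g], na.rm = TRUE); d <- n2 - cc
    tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test <- "fisher_exact"
      p <- stats::fisher.test(tab)$p.value
    } else {
      test <- "chi_square"
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
    }
    row <- data.frame(
      variable = spec,
      group1_summary = sprintf("%d (%d%%)", a, round(100 * a / n1)),
      group2_summary = sprintf("%d (%d%%)", cc, round(100 * cc / n2)),
      group1_count = a, group2_count = cc,
      test_used = test, p_value = p, stringsAsFactors = FALSE)
  } else if (is.numeric(x)) {
    x1 <- x[g]; x2 <- x[!g]
    normal_ok <- function(v) {
      v <- v[!is.na(v)]
      length(v) >= 30 && stats::sd(v) > 0 && abs(.skewness(v)) <= 1
    }
    if (stats::sd(c(x1, x2), na.rm = TRUE) == 0) {
      # degenerate: no variation at all, nothing to test
      test <- "wilcoxon"
      p <- 1
    } else if (normal_ok(x1) && normal_ok(x2)) {
      test <- "t_test"
      p <- stats::t.test(x1, x2)$p.value
    } else {
      test <- "wilcoxon"
      p <- stats::wilcox.test(x1, x2, exact = FALSE)$p.value
    }
    smry <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      sprintf("%g [%g-%g]", q[2], q[1], q[3])
    }
    row <- data.frame(variable = spec, group1_summary = smry(x1),
                      group2_summary = smry(x2),
                      group1_count = NA_real_, group2_count = NA_real_,
                      test_used = test, p_value = p,
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(factor(x), factor(g, levels = c(TRUE, FALSE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test <- "fisher_exact"
      p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    } else {
      test <- "chi_square"
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
    }
    mode1 <- names(which.max(tab[, 1]))
    row <- data.frame(
      variable = spec,
      group1_summary = sprintf("%d levels, mode %s", nrow(tab), mode1),
      group2_summary = sprintf("%d levels", nrow(tab)),
      group1_count = NA_real_, group2_count = NA_real_,
      test_used = test, p_value = p, stringsAsFactors = FALSE)
  }
  row
}

#' Multivariable logistic regression with Wald intervals
#'
#' Maximum-likelihood logistic fit of a binary outcome item on binary
#' covariate items, reported as odds ratios with Wald confidence
#' intervals.  The default subset restricts to patients whose first call
#' was a sole-criterion hypotension call — the development model of
#' fluid administration on respiratory-ward / cardiac-diagnosis /
#' heart-failure-unit indicators.
#'
#' @param cohort a [met_cohort()].
#' @param outcome outcome item specification (default `"iv_fluid"`,
#'   read from the first call).
#' @param covariates character vector of covariate specifications.
#' @param subset `"first_call_hypotension"` (default) or `"all"`.
#' @param ci_level Wald interval level.
#' @return object of class `logistic_fit`: coefficients (estimate, se),
#'   odds ratios with intervals and p-values, `converged`, `n_used`.
#' @export
fit_logistic <- function(cohort, outcome = "iv_fluid",
                         covariates = c("location=respiratory_ward",
                                        "diagnosis_group=circulatory_cardiac",
                                        "clinical_unit=heart_failure"),
                         subset = c("first_call_hypotension", "all"),
                         ci_level = 0.95) {
  subset <- match.arg(subset)
  pt <- patient_table(cohort)
  if (subset == "first_call_hypotension") {
    pt <- pt[pt$first_triggers == "hypotension_sbp_le_90", , drop = FALSE]
  }
  y <- as.numeric(resolve_variable(pt, outcome))
  X <- lapply(covariates, function(v) as.numeric(resolve_variable(pt, v)))
  names(X) <- covariates
  df <- data.frame(y = y, X, check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10 * length(covariates)) {
    stop("too few complete cases for ", length(covariates), " covariates")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  converged <- fit$converged && !separation && all(abs(est) < 15)
  z <- stats::qnorm((1 + ci_level) / 2)
  terms <- gsub("`", "", rownames(sm)[-1], fixed = TRUE)
  ors <- data.frame(
    term = terms,
    or = exp(est[-1]),
    ci_low = exp(est[-1] - z * se[-1]),
    ci_high = exp(est[-1] + z * se[-1]),
    p = sm[-1, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(ors) <- NULL
  structure(list(outcome = outcome,
                 coefficients = cbind(estimate = est, se = se),
                 odds_ratios = ors, converged = converged,
                 n_used = nrow(df), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model for %s (n = %d, %s)\n", x$outcome, x$n_used,
              if (x$converged) "converged" else "NOT CONVERGED"))
  o <- x$odds_ratios
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  %-40s OR %.2f [95%%CI %.2f-%.2f] p=%.3g\n", o$term[i],
                o$or[i], o$ci_low[i], o$ci_high[i], o$p[i]))
  }
  invisible(x)
}
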