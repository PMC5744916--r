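test_that("odds ratio arithmetic, zero-cell policy, and symmetry", {
  # fluid at hypotension vs other calls: 1714/2459 v 739/5477
  o <- odds_ratio(c(1714, 745, 739, 4738))
  expect_equal(unname(o["or"]), (1714 * 4738) / (745 * 739),
               tolerance = 1e-12)
  expect_lt(abs(o["or"] - 14.75), 0.01)
  expect_true(o["ci_low"] < o["or"] && o["or"] < o["ci_high"])
  # symmetric table: OR 1, CI straddles 1
  s <- odds_ratio(c(5, 5, 5, 5))
  expect_equal(unname(s["or"]), 1)
  expect_lt(s["ci_low"], 1); expect_gt(s["ci_high"], 1)
  # zero cell handled by the +0.5 correction
  z <- odds_ratio(c(5, 0, 5, 5))
  expect_true(is.finite(z["or"]) && z["or"] > 0)
  # row/column swap inverts the OR
  a <- odds_ratio(c(20, 10, 5, 15))
  b <- odds_ratio(c(5, 15, 20, 10))
  expect_equal(unname(a["or"]), 1 / unname(b["or"]), tolerance = 1e-12)
  expect_error(odds_ratio(c(0, 0, 3, 4)), "margin")
})

test_that("comparison battery picks tests per policy and finds the fixture margins", {
  co <- build_fixture(fixture_margins(2))
  pt <- patient_table(co)
  hypo <- pt$first_triggers == "hypotension_sbp_le_90"
  fl <- metminer:::cell_has(pt$first_interventions, "iv_fluid")
  g <- ifelse(hypo, fl, NA)        # fluid vs no-fluid among hypotension
  rows <- compare_groups(co, g,
                         c("clinical_unit=heart_failure", "ecg",
                           "multiple_met", "los_days"))
  hf <- rows[rows$variable == "clinical_unit=heart_failure", ]
  expect_equal(hf$group1_count, 46)
  expect_equal(hf$group2_count, 79)
  expect_equal(hf$group1_summary, "46 (3%)")
  expect_equal(hf$group2_summary, "79 (11%)")
  expect_lt(hf$p_value, 0.001)
  expect_equal(rows$test_used[rows$variable == "ecg"], "chi_square")
  expect_lt(rows$p_value[rows$variable == "multiple_met"], 0.001)
})

test_that("identical groups give p about 1 everywhere", {
  co <- generate_cohort(generator_params(n_patients = 150, seed = 2))
  ep2 <- co$episodes; ca2 <- co$calls
  ep2$patient_id <- paste0("X", ep2$patient_id)
  ca2$patient_id <- paste0("X", ca2$patient_id)
  ca2$call_id <- paste0("X", ca2$call_id)
  twin <- met_cohort(rbind(co$episodes, ep2), rbind(co$calls, ca2))
  g <- !startsWith(patient_table(twin)$patient_id, "X")
  rows <- compare_groups(twin, g, c("iv_fluid", "died_in_hospital",
                                    "age_years", "los_days"))
  expect_true(all(rows$p_value > 0.97))
})

test_that("a known location shift is detected by the Wilcoxon path", {
  set.seed(77)
  hits <- vapply(1:50, function(i) {
    x <- stats::rlnorm(500, log(9), 1.07)
    y <- stats::rlnorm(500, log(9), 1.07) + 3
    stats::wilcox.test(x, y, exact = FALSE)$p.value < 0.001
  }, NA)
  expect_gte(mean(hits), 0.98)
})

test_that("the chi-square path keeps its type-I error near nominal under independence", {
  set.seed(1)
  pt0 <- function(x) data.frame(died_in_hospital = x)
  pvals <- vapply(1:1000, function(i) {
    x <- stats::runif(500) < 0.3
    g <- stats::runif(500) < 0.5
    metminer:::.compare_one(pt0(x), g, "died_in_hospital")$p_value
  }, 0)
  expect_lte(mean(pvals < 0.05), 0.06)
})

test_that("single-covariate logistic regression reproduces the analytic 2x2 OR", {
  co <- generate_cohort(generator_params(n_patients = 6000, seed = 13))
  f <- fit_logistic(co, covariates = "clinical_unit=heart_failure")
  pt <- patient_table(co)
  hypo <- pt$first_triggers == "hypotension_sbp_le_90"
  fl <- metminer:::cell_has(pt$first_interventions, "iv_fluid")
  hf <- pt$clinical_unit == "heart_failure"
  tab <- c(sum(hypo & hf & fl), sum(hypo & hf & !fl),
           sum(hypo & !hf & fl), sum(hypo & !hf & !fl))
  expect_equal(f$odds_ratios$or[1], unname(odds_ratio(tab)["or"]),
               tolerance = 1e-6)
})

test_that("separation is flagged rather than silently reported", {
  co <- tiny_cohort()
  # build a cohort where a covariate perfectly predicts fluid
  n <- 80
  ep <- co$episodes[rep(1, n), ]
  ep$patient_id <- sprintf("P%03d", 1:n)
  ep$clinical_unit <- rep(c("heart_failure", "orthopaedics"), each = n / 2)
  ca <- co$calls[rep(1, n), ]
  ca$call_id <- sprintf("C%03d", 1:n)
  ca$patient_id <- ep$patient_id
  ca$triggers <- "hypotension_sbp_le_90"
  ca$interventions <- rep(c("", "iv_fluid"), each = n / 2)
  sep_co <- met_cohort(ep, ca)
  f <- fit_logistic(sep_co, covariates = "clinical_unit=heart_failure")
  expect_false(f$converged)
})

test_that("null covariates give odds ratios near 1 with covering intervals", {
  # gender is independent of fluid administration in the generator, so
  # its fitted OR should be null: the 95% CI should cover 1 in about 95%
  # of replicates
  covered <- vapply(1:40, function(i) {
    co <- generate_cohort(generator_params(n_patients = 2000,
                                           seed = 500 + i))
    f <- fit_logistic(co, covariates = "gender=male")
    f$odds_ratios$ci_low[1] <= 1 && 1 <= f$odds_ratios$ci_high[1]
  }, NA)
  expect_gte(mean(covered), 0.85)
})
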