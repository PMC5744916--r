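test_that("confusion counts agree with a brute-force recount", {
  co <- generate_cohort(generator_params(n_patients = 400, seed = 23))
  cfg <- policy_config()
  cm <- classify_predictions(co, cfg)
  # independent recount by iterating over patients
  tp <- fp <- tn <- fn <- 0
  for (pid in unique(co$calls$patient_id)) {
    pc <- co$calls[co$calls$patient_id == pid, ]
    pc <- pc[order(pc$timestamp, pc$call_id), ]
    first <- pc[1, ]
    if (first$triggers != "hypotension_sbp_le_90") next
    ep <- co$episodes[co$episodes$patient_id == pid, ]
    elig <- first$location != "respiratory_ward" &&
      ep$diagnosis_group != "circulatory_cardiac" &&
      ep$clinical_unit != "heart_failure"
    given <- grepl("iv_fluid", first$interventions, fixed = TRUE)
    if (elig && given) tp <- tp + 1
    else if (elig) fp <- fp + 1
    else if (given) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(cm$tp, tp); expect_equal(cm$fp, fp)
  expect_equal(cm$tn, tn); expect_equal(cm$fn, fn)
  # marginals tie out with the eligibility partition
  part <- eligible_patients(co, cfg)
  expect_equal(cm$tp + cm$fp, length(part$eligible))
  expect_equal(cm$tn + cm$fn, length(part$ineligible_with_trigger))
})

test_that("counterfactual accounting conserves calls and is idempotent", {
  co <- build_fixture(fixture_margins(3))
  rep1 <- counterfactual(co)
  w <- rep1$without_algorithm; a <- rep1$with_algorithm
  expect_equal(unname(w["total_calls"]),
               unname(a["total_calls"]) + rep1$averted_calls)
  expect_true(all(a <= w))
  rep2 <- counterfactual(rep1$with_cohort)
  expect_equal(rep2$averted_calls, 0)
  expect_equal(unname(rep2$reductions["total_calls"]), 0)
})

test_that("no eligible patients means zero reduction everywhere", {
  co <- build_fixture(fixture_margins(3))
  cfg <- policy_config(excluded_units = met_vocab$clinical_units)
  r <- counterfactual(co, cfg)
  expect_equal(unname(r$averted_calls), 0)
  expect_true(all(r$reductions == 0))
})

test_that("a fully eligible trigger-only cohort reduces 100% of calls and patients", {
  n <- 20
  ep <- tiny_cohort()$episodes[rep(1, n), ]
  ep$patient_id <- sprintf("P%03d", 1:n)
  ca <- tiny_cohort()$calls[rep(1, 2 * n), ]
  ca$call_id <- sprintf("C%03d", 1:(2 * n))
  ca$patient_id <- rep(ep$patient_id, each = 2)
  ca$timestamp <- rep(c("2013-01-02T10:00:00", "2013-01-03T10:00:00"), n)
  ca$triggers <- "hypotension_sbp_le_90"
  co <- met_cohort(ep, ca)
  r <- counterfactual(co)
  expect_equal(unname(r$reductions["total_calls"]), 100)
  expect_equal(unname(r$reductions["total_patients_with_calls"]), 100)
})

test_that("true-positive vs false-positive comparison reproduces the detail margins", {
  co <- build_fixture(fixture_margins(4))
  rows <- compare_tp_fp(co)
  adv <- rows[rows$variable == "advice_only", ]
  expect_equal(adv$group1_count, 0)
  expect_equal(adv$group2_count, 233)
  ecg <- rows[rows$variable == "ecg", ]
  expect_equal(ecg$group1_count, 511)
  expect_equal(ecg$group2_count, 113)
  # direct recount of ECG flags among the groups
  d <- metminer:::first_call_decisions(co, policy_config())
  tp_ids <- d$patient_id[d$trigger_matched & d$eligible & d$fluid_given]
  fc <- first_calls(co)
  expect_equal(sum(metminer:::cell_has(
    fc$interventions[fc$patient_id %in% tp_ids], "ecg")), 511)
  dec <- rows[rows$variable == "died_in_hospital", ]
  expect_equal(dec$group1_count, 106)
  expect_equal(dec$group2_count, 25)
  expect_lt(adv$p_value, 1e-10)
})

test_that("impact invariants hold across random cohorts", {
  for (seed in 1:10) {
    co <- generate_cohort(generator_params(n_patients = 120,
                                           seed = 100 + seed))
    r <- counterfactual(co)
    w <- r$without_algorithm; a <- r$with_algorithm
    expect_equal(unname(w["total_calls"] - a["total_calls"]),
                 r$averted_calls)
    expect_true(all(a <= w))
    part <- eligible_patients(co)
    expect_equal(r$confusion$tp + r$confusion$fp, length(part$eligible))
    expect_equal(sum(part$sizes), length(unique(co$calls$patient_id)))
  }
})
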