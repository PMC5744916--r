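test_that("a small CSV pair reads into a validated cohort with calls in time order", {
  dir <- withr::local_tempdir()
  write_cohort(tiny_cohort(), dir)
  co <- read_cohort(dir)
  expect_s3_class(co, "met_cohort")
  expect_equal(nrow(co$episodes), 3)
  expect_equal(nrow(co$calls), 5)
  p1 <- co$calls[co$calls$patient_id == "P1", ]
  expect_true(all(diff(order(p1$timestamp)) > 0))
})

test_that("referential and vocabulary violations are reported with offending values", {
  co <- tiny_cohort()
  bad <- co$calls
  bad$patient_id[3] <- "P999"
  expect_error(met_cohort(co$episodes, bad),
               "referential error.*P999")
  bad2 <- co$calls
  bad2$triggers[1] <- "not_a_trigger"
  expect_error(met_cohort(co$episodes, bad2),
               "vocabulary error.*not_a_trigger")
  expect_error(met_cohort(co$episodes[, -2], co$calls),
               "schema error.*age_years")
})

test_that("mutual-exclusivity invariants are enforced", {
  co <- tiny_cohort()
  bad <- co$calls
  bad$interventions[4] <- "advice_only;ecg"
  expect_error(met_cohort(co$episodes, bad), "advice_only")
  bad2 <- co$calls
  bad2$outcome_flags[1] <- "died_at_call;transferred_to_icu"
  expect_error(met_cohort(co$episodes, bad2), "died_at_call")
  bad3 <- co$calls
  bad3$triggers[2] <- ""
  expect_error(met_cohort(co$episodes, bad3), "empty trigger set")
})

test_that("write/read round-trip is the identity and writing is byte-stable", {
  co <- generate_cohort(generator_params(n_patients = 200, seed = 11))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  back <- read_cohort(d1)
  expect_equal(back$episodes, co$episodes)
  expect_equal(back$calls, co$calls)
  write_cohort(co, d2)
  expect_identical(readLines(file.path(d1, "calls.csv")),
                   readLines(file.path(d2, "calls.csv")))
  expect_identical(readLines(file.path(d1, "episodes.csv")),
                   readLines(file.path(d2, "episodes.csv")))
})

test_that("empty cohorts write header-only CSVs and counts match on large cohorts", {
  co0 <- met_cohort(tiny_cohort()$episodes[0, ], tiny_cohort()$calls[0, ])
  dir <- withr::local_tempdir()
  write_cohort(co0, dir)
  expect_length(readLines(file.path(dir, "episodes.csv")), 1)
  expect_length(readLines(file.path(dir, "calls.csv")), 1)
  co <- generate_cohort(generator_params(n_patients = 1000, seed = 3))
  write_cohort(co, dir)
  expect_length(readLines(file.path(dir, "episodes.csv")),
                nrow(co$episodes) + 1)
  expect_length(readLines(file.path(dir, "calls.csv")),
                nrow(co$calls) + 1)
})

test_that("first_calls picks the timestamp-minimal call with call-id tie-break", {
  co <- tiny_cohort()
  fc <- first_calls(co)
  expect_equal(nrow(fc), 3)
  expect_equal(fc$call_id[fc$patient_id == "P1"], "C1")
  # forced tie on timestamp
  calls <- co$calls
  calls$timestamp[2] <- calls$timestamp[1]
  calls$call_id[1:2] <- c("C9", "C0")
  co2 <- met_cohort(co$episodes, calls)
  expect_equal(first_calls(co2)$call_id[1], "C0")
})

test_that("sole_trigger is exact set equality with one criterion", {
  co <- tiny_cohort()
  fc <- first_calls(co)
  c1 <- fc[fc$patient_id == "P1", ]
  expect_true(sole_trigger(c1, "hypotension_sbp_le_90"))
  combo <- co$calls[co$calls$call_id == "C2", ]
  expect_false(sole_trigger(combo, "hypotension_sbp_le_90"))
  c4 <- co$calls[co$calls$call_id == "C4", ]
  expect_false(sole_trigger(c4, "hypotension_sbp_le_90"))
  expect_true(sole_trigger(c4, "hr_ge_140"))
})

test_that("generated cohorts stay inside the closed vocabularies", {
  co <- generate_cohort(generator_params(n_patients = 400, seed = 5))
  expect_silent(validate_cohort <- metminer:::validate_cohort(co))
  expect_true(all(unlist(metminer:::split_multi(co$calls$triggers)) %in%
                    met_vocab$triggers))
  expect_true(all(co$episodes$clinical_unit %in% met_vocab$clinical_units))
})
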