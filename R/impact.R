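# Counterfactual evaluation of the pre-emptive policy on a held-out
# cohort: prediction confusion matrix over first-call-trigger patients,
# averted-call accounting, and reduction percentages.

# which calls match the policy trigger condition
trigger_matched_calls <- function(cohort, config) {
  if (config$require_sole_trigger) {
    cohort$calls$triggers == config$trigger
  } else {
    cell_has(cohort$calls$triggers, config$trigger)
  }
}

#' Prediction confusion matrix of the policy
#'
#' Over patients whose first call matched the trigger condition, the
#' policy's prediction (eligible = would have received fluid under the
#' algorithm) is crossed with what actually happened (intravenous fluid
#' among the first call's interventions): TP eligible and fluid given,
#' FP eligible but not given, TN ineligible and not given, FN ineligible
#' but given.
#'
#' @param cohort a [met_cohort()].
#' @param config a [policy_config()].
#' @return list of class `confusion_counts` with integer `tp`, `fp`,
#'   `tn`, `fn` and `n_trigger_patients`.
#' @export
classify_predictions <- function(cohort, config = policy_config()) {
  d <- first_call_decisions(cohort, config)
  d <- d[d$trigger_matched, , drop = FALSE]
  structure(list(
    tp = sum(d$eligible & d$fluid_given),
    fp = sum(d$eligible & !d$fluid_given),
    tn = sum(!d$eligible & !d$fluid_given),
    fn = sum(!d$eligible & d$fluid_given),
    n_trigger_patients = nrow(d)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  n <- x$n_trigger_patients
  pc <- function(k) sprintf("%d (%.1f%%)", k, round(100 * k / n, 1))
  cat("Prediction vs actual fluid at first trigger call",
      sprintf("(n = %d patients):\n", n))
  cat("  true positives: ", pc(x$tp), "\n")
  cat("  false positives:", pc(x$fp), "\n")
  cat("  true negatives: ", pc(x$tn), "\n")
  cat("  false negatives:", pc(x$fn), "\n")
  invisible(x)
}

#' Counterfactual impact of the policy
#'
#' Removes from the call stream every trigger-matched call of a
#' policy-eligible patient (eligibility judged on the first call) and
#' recomputes the call and patient totals, mirroring the published
#' impact table: total calls, patients with at least one call, patients
#' whose first call matched the trigger, and trigger-matched calls, each
#' with its percentage reduction.
#'
#' @param cohort a [met_cohort()].
#' @param config a [policy_config()].
#' @return object of class `impact_report`: `without_algorithm` and
#'   `with_algorithm` count tuples, `averted_calls`, `reductions`
#'   (percentages, one decimal), the prediction `confusion`, and the
#'   reduced cohort (`with_cohort`).
#' @export
counterfactual <- function(cohort, config = policy_config()) {
  tuple <- function(co) {
    matched <- trigger_matched_calls(co, config)
    fc <- first_calls(co)
    fc_matched <- if (config$require_sole_trigger) {
      fc$triggers == config$trigger
    } else {
      cell_has(fc$triggers, config$trigger)
    }
    c(total_calls = nrow(co$calls),
      total_patients_with_calls = length(unique(co$calls$patient_id)),
      first_call_trigger_patients = sum(fc_matched),
      trigger_calls = sum(matched))
  }
  without <- tuple(cohort)
  elig <- eligible_patients(cohort, config)$eligible
  drop <- trigger_matched_calls(cohort, config) &
    cohort$calls$patient_id %in% elig
  reduced <- met_cohort(cohort$episodes,
                        cohort$calls[!drop, , drop = FALSE],
                        period_label = cohort$period_label,
                        validate = FALSE, .canonical = TRUE)
  with <- tuple(reduced)
  reductions <- round(100 * (without - with) /
                        pmax(without, 1), 1)
  reductions[without == 0] <- 0
  structure(list(
    without_algorithm = without,
    with_algorithm = with,
    averted_calls = unname(without["trigger_calls"] -
                             with["trigger_calls"]),
    reductions = reductions,
    confusion = classify_predictions(cohort, config),
    with_cohort = reduced,
    config = config
  ), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  w <- x$without_algorithm; a <- x$with_algorithm; r <- x$reductions
  lab <- c(total_calls = "MET calls (total)",
           total_patients_with_calls = "patients with >=1 MET call",
           first_call_trigger_patients = "patients, first call = trigger",
           trigger_calls = "MET calls for trigger")
  cat(sprintf("Counterfactual impact (%s trigger, averted calls: %d)\n",
              x$config$trigger, x$averted_calls))
  for (k in names(lab)) {
    cat(sprintf("  %-32s %6d -> %6d (%.1f%% reduction)\n", lab[k], w[k],
                a[k], r[k]))
  }
  print(x$confusion)
  invisible(x)
}

#' Compare true-positive and false-positive patients
#'
#' Interventions and outcomes of trigger patients who did receive fluid
#' and were predicted to (true positives) versus those predicted to but
#' who did not (false positives); delegates to [compare_groups()].
#'
#' @param cohort a [met_cohort()].
#' @param config a [policy_config()].
#' @param variables variable specifications; defaults cover the
#'   published intervention and outcome rows.
#' @return a `comparison_table` (group 1 = true positives).
#' @export
compare_tp_fp <- function(cohort, config = policy_config(),
                          variables = c("advice_only", "ecg", "abg",
                                        "blood_test", "xray", "oxygen",
                                        "medication_change",
                                        "non_invasive_ventilation",
                                        "died_in_hospital",
                                        "transferred_to_icu",
                                        "multiple_met")) {
  d <- first_call_decisions(cohort, config)
  g <- rep(NA, nrow(d))
  g[d$trigger_matched & d$eligible & d$fluid_given] <- TRUE
  g[d$trigger_matched & d$eligible & !d$fluid_given] <- FALSE
  compare_groups(cohort, g, variables)
}
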