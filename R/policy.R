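# The pre-emptive management decision rule: nurse-initiated intravenous
# fluid at qualifying hypotension calls, with categorical exclusions for
# patient groups in whom fluid was not the usual response (respiratory
# ward, cardiac admission diagnosis, heart-failure unit).

#' Pre-emptive policy configuration
#'
#' Defaults encode the published flow chart: a sole-criterion hypotension
#' trigger, with the respiratory ward, circulatory/cardiac admission
#' diagnoses and the heart-failure unit excluded; eligible calls receive
#' intravenous fluid without MET activation, everything else activates
#' the MET.
#'
#' @param trigger qualifying trigger criterion.
#' @param require_sole_trigger if `TRUE` (default) the trigger must be
#'   the call's only criterion; combination calls go to the MET.
#' @param excluded_locations,excluded_diagnoses,excluded_units label
#'   sets drawn from the respective vocabularies.
#' @return list of class `policy_config`.
#' @export
policy_config <- function(trigger = "hypotension_sbp_le_90",
                          require_sole_trigger = TRUE,
                          excluded_locations = "respiratory_ward",
                          excluded_diagnoses = "circulatory_cardiac",
                          excluded_units = "heart_failure") {
  stopifnot(trigger %in% met_vocab$triggers,
            all(excluded_locations %in% met_vocab$locations),
            all(excluded_diagnoses %in% met_vocab$diagnosis_groups),
            all(excluded_units %in% met_vocab$clinical_units))
  structure(list(trigger = trigger,
                 require_sole_trigger = isTRUE(require_sole_trigger),
                 excluded_locations = excluded_locations,
                 excluded_diagnoses = excluded_diagnoses,
                 excluded_units = excluded_units,
                 action_if_eligible = "administer_iv_fluid_no_met",
                 action_otherwise = "activate_met"),
            class = "policy_config")
}

# Vectorised decision core over parallel vectors of call/episode
# attributes; returns a data frame of trigger match, eligibility and
# reason labels.
.decide_vec <- function(trigger_cells, locations, units, diagnoses,
                        config) {
  matched <- if (config$require_sole_trigger) {
    trigger_cells == config$trigger
  } else {
    cell_has(trigger_cells, config$trigger)
  }
  r_loc <- matched & locations %in% config$excluded_locations
  r_dx <- matched & diagnoses %in% config$excluded_diagnoses
  r_unit <- matched & units %in% config$excluded_units
  eligible <- matched & !r_loc & !r_dx & !r_unit
  reasons <- character(length(matched))
  reasons[r_loc] <- "excluded_location"
  reasons[r_dx] <- ifelse(nzchar(reasons[r_dx]),
                          paste(reasons[r_dx], "excluded_diagnosis",
                                sep = ";"), "excluded_diagnosis")
  reasons[r_unit] <- ifelse(nzchar(reasons[r_unit]),
                            paste(reasons[r_unit], "excluded_unit",
                                  sep = ";"), "excluded_unit")
  data.frame(trigger_matched = matched, eligible = eligible,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Apply the decision rule to one call
#'
#' @param call one row of a cohort's `calls` table.
#' @param episode the matching row of the `episodes` table.
#' @param config a [policy_config()].
#' @return list of class `met_decision`: `patient_id`, `call_id`,
#'   `eligible`, `action`, and `reasons` (matched exclusion labels;
#'   empty when eligible, and also empty when the trigger condition
#'   itself did not hold).
#' @export
decide <- function(call, episode, config = policy_config()) {
  stopifnot(call$patient_id[1] == episode$patient_id[1])
  d <- .decide_vec(join_multi(split_multi(as.character(call$triggers[1]))),
                   as.character(call$location[1]),
                   as.character(episode$clinical_unit[1]),
                   as.character(episode$diagnosis_group[1]), config)
  structure(list(
    patient_id = call$patient_id[1],
    call_id = call$call_id[1],
    eligible = d$eligible,
    action = if (d$eligible) config$action_if_eligible
             else config$action_otherwise,
    reasons = if (nzchar(d$reasons)) strsplit(d$reasons, ";")[[1]]
              else character(0)
  ), class = "met_decision")
}

#' @export
print.met_decision <- function(x, ...) {
  cat(sprintf("call %s (patient %s): %s%s\n", x$call_id, x$patient_id,
              x$action,
              if (length(x$reasons))
                paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# First-call decisions for every patient with at least one call.
first_call_decisions <- function(cohort, config = policy_config()) {
  fc <- first_calls(cohort)
  ep <- cohort$episodes[match(fc$patient_id, cohort$episodes$patient_id),
                        , drop = FALSE]
  d <- .decide_vec(fc$triggers, fc$location, ep$clinical_unit,
                   ep$diagnosis_group, config)
  cbind(data.frame(patient_id = fc$patient_id,
                   call_id = fc$call_id,
                   fluid_given = cell_has(fc$interventions, "iv_fluid"),
                   stringsAsFactors = FALSE),
        d)
}

#' Patient-level eligibility partition
#'
#' Classifies every patient with at least one call by the decision on
#' their first call: policy-eligible, trigger-matched but excluded, or
#' first call not matching the trigger condition at all.  The three set
#' sizes sum to the number of patients with calls.
#'
#' @param cohort a [met_cohort()].
#' @param config a [policy_config()].
#' @return list with character-vector elements `eligible`,
#'   `ineligible_with_trigger`, `no_trigger` and integer `sizes`.
#' @export
eligible_patients <- function(cohort, config = policy_config()) {
  d <- first_call_decisions(cohort, config)
  out <- list(
    eligible = d$patient_id[d$eligible],
    ineligible_with_trigger = d$patient_id[d$trigger_matched & !d$eligible],
    no_trigger = d$patient_id[!d$trigger_matched]
  )
  out$sizes <- vapply(out[1:3], length, 0L)
  out
}
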