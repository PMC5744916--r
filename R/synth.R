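# Synthetic MET cohort generator.
#
# The generator emulates the published margins of a two-period MET service
# audit: first-call trigger frequencies, admitting unit / ward / diagnosis
# composition, a logistic model for intravenous fluid administration at
# hypotension calls (reduced odds on the respiratory ward, with a cardiac
# admission diagnosis, or under the heart-failure team), shifted-Poisson
# repeat-call multiplicity, stratified in-hospital mortality, and
# log-normal length-of-stay and laboratory values.

# first-call trigger category counts (denominator 7936 patients)
.trigger_counts <- c(
  hypotension_sbp_le_90 = 2459, hr_ge_140 = 1085, gcs_decrease = 962,
  spo2_le_90 = 618, rr_ge_36 = 429, sbp_ge_200 = 359,
  serious_concern = 299, hr_le_40 = 291, pain = 252, seizures = 116,
  arrest_cpr = 76, rr_le_6 = 48, uncontrolled_bleeding = 33,
  "hypotension_sbp_le_90+gcs_decrease" = 52,
  "hypotension_sbp_le_90+hr_le_40" = 45,
  "hypotension_sbp_le_90+hr_ge_140" = 43,
  "hypotension_sbp_le_90+spo2_le_90" = 36,
  "hypotension_sbp_le_90+rr_ge_36" = 11,
  "hypotension_sbp_le_90+other" = 80,
  other_multi = 642
)

# admitting unit / call location / diagnosis counts from the hypotension
# comparison table (denominator 2459); remainder assigned to the catch-all
# label
.unit_counts <- c(
  orthopaedics = 279, breast_endocrine_surgery = 42, burns = 40,
  colorectal_surgery = 84, plastics = 65, urology = 42,
  heart_failure = 125, psychiatry = 22, general_respiratory = 43,
  cystic_fibrosis = 12, lung_transplantation = 33, neurology = 37,
  other_unit = 2459 - 824
)
.location_counts <- c(
  general_surgery_burns_ward = 164, trauma_orthopaedics_ward = 259,
  trauma_neurosurgery_ward = 127, general_surgery_ward = 157,
  cardiology_cardiothoracic_ward = 488, psychiatry_area = 22,
  respiratory_ward = 67, other_ward = 2459 - 1284
)
.diagnosis_counts <- c(
  circulatory_cardiac = 562, respiratory = 226, neurological = 159,
  hepatobiliary = 77, ear_nose_mouth_throat = 37, psychiatric = 27,
  musculoskeletal = 380, gastroenterology = 266, infectious_diseases = 131,
  renal_urology = 124, myeloproliferative = 92, poisonings_toxicology = 88,
  endocrine_metabolic = 57, skin_breast = 52, burns_dx = 38,
  haematology = 36, alcohol_drug = 5, other_dx = 40 + (2459 - 2397)
)

# log-normal parameters matched to a median/IQR by quantile matching
.lnorm_match <- function(median, q1, q3) {
  c(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Parameters of the synthetic MET cohort generator
#'
#' Defaults reproduce the study conditions: trigger-category frequencies
#' of the first-call frequency table, unit/ward/diagnosis composition of
#' the hypotension cohort table, a fluid-administration logistic model
#' with adjusted odds ratios 0.41 (respiratory ward), 0.61 (cardiac
#' diagnosis) and 0.29 (heart-failure unit) and an intercept calibrated
#' so the marginal fluid rate at hypotension calls is 0.70, mean calls
#' per patient 13656/7936, stratified in-hospital mortality (0.05 for
#' sole-hypotension first calls, 0.11 otherwise), and length of stay
#' log-normal with median 9 and IQR 4-17 days.
#'
#' @param n_patients number of patients (each has at least one call).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of `(seed, params)`.
#' @param trigger_probs named probability vector over first-call trigger
#'   categories (13 sole criteria plus the multi-criterion categories).
#' @param unit_probs,location_probs,diagnosis_probs named probability
#'   vectors over the respective vocabularies.
#' @param fluid_model named log-odds terms `respiratory_ward`,
#'   `cardiac_diagnosis`, `heart_failure_unit`, plus `target_rate`, the
#'   marginal fluid rate at hypotension calls used to calibrate the
#'   intercept.
#' @param fluid_other_rate fluid rate at non-hypotension calls.
#' @param repeat_call_mean expected calls per patient (>= 1); counts are
#'   1 + Poisson(mean - 1).
#' @param mortality_probs `c(hypotension = , other = )` in-hospital death
#'   probabilities by first-call type.
#' @param los_model `c(meanlog = , sdlog = )` for length of stay in days.
#' @return a validated list of class `generator_params`.
#' @export
generator_params <- function(n_patients = 7936, seed = 1L,
                             trigger_probs = .trigger_counts / sum(.trigger_counts),
                             unit_probs = .unit_counts / sum(.unit_counts),
                             location_probs = .location_counts / sum(.location_counts),
                             diagnosis_probs = .diagnosis_counts / sum(.diagnosis_counts),
                             fluid_model = c(respiratory_ward = log(0.41),
                                             cardiac_diagnosis = log(0.61),
                                             heart_failure_unit = log(0.29),
                                             target_rate = 0.70),
                             fluid_other_rate = 739 / 5477,
                             repeat_call_mean = 13656 / 7936,
                             mortality_probs = c(hypotension = 0.05,
                                                 other = 0.11),
                             los_model = .lnorm_match(9, 4, 17)) {
  p <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
            trigger_probs = trigger_probs, unit_probs = unit_probs,
            location_probs = location_probs,
            diagnosis_probs = diagnosis_probs, fluid_model = fluid_model,
            fluid_other_rate = fluid_other_rate,
            repeat_call_mean = repeat_call_mean,
            mortality_probs = mortality_probs, los_model = los_model)
  chk_probs <- function(v, what) {
    if (any(v < 0 | v > 1)) {
      stop("invalid probability vector for ", what)
    }
    if (abs(sum(v) - 1) > 1e-9) {
      stop("probability vector for ", what, " does not sum to 1")
    }
  }
  chk_probs(p$trigger_probs, "trigger_probs")
  chk_probs(p$unit_probs, "unit_probs")
  chk_probs(p$location_probs, "location_probs")
  chk_probs(p$diagnosis_probs, "diagnosis_probs")
  stopifnot(p$n_patients >= 1, p$repeat_call_mean >= 1,
            p$fluid_other_rate >= 0, p$fluid_other_rate <= 1)
  structure(p, class = "generator_params")
}

# Solve for the logistic intercept giving the requested marginal fluid
# rate at hypotension calls, under independent covariate draws.
calibrate_fluid_intercept <- function(fluid_model, p_resp, p_card, p_hf) {
  beta <- fluid_model[c("respiratory_ward", "cardiac_diagnosis",
                        "heart_failure_unit")]
  target <- fluid_model[["target_rate"]]
  combos <- expand.grid(r = 0:1, c = 0:1, h = 0:1)
  w <- with(combos,
            (r * p_resp + (1 - r) * (1 - p_resp)) *
            (c * p_card + (1 - c) * (1 - p_card)) *
            (h * p_hf + (1 - h) * (1 - p_hf)))
  lp <- as.matrix(combos) %*% beta
  stats::uniroot(function(b0) sum(w * stats::plogis(b0 + lp)) - target,
                 c(-10, 10), tol = 1e-10)$root
}

# Vectorised canonical join of per-call flag columns: `flags` is a named
# list of logical vectors; names must be supplied sorted.
.join_flags <- function(flags, n) {
  cell <- character(n)
  for (lab in names(flags)) {
    f <- flags[[lab]]
    cell <- ifelse(f, ifelse(cell == "", lab, paste(cell, lab, sep = ";")),
                   cell)
  }
  cell
}

#' Generate a synthetic MET cohort
#'
#' @param params a [generator_params()] object.
#' @param period_label label for the returned cohort.
#' @return a [met_cohort()].  The same `(seed, params)` always yields an
#'   identical cohort; the caller's RNG state is left untouched.
#' @export
generate_cohort <- function(params = generator_params(),
                            period_label = "training") {
  stopifnot(inherits(params, "generator_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)
  n <- params$n_patients

  pid <- sprintf("P%06d", seq_len(n))
  gender <- sample(c("male", "female", "unknown"), n, TRUE,
                   prob = c(0.48, 0.48, 0.04))
  age <- pmin(pmax(round(stats::rnorm(n, 66, 17)), 18), 100)
  unit <- sample(names(params$unit_probs), n, TRUE, params$unit_probs)
  dx <- sample(names(params$diagnosis_probs), n, TRUE,
               params$diagnosis_probs)
  loc <- sample(names(params$location_probs), n, TRUE,
                params$location_probs)
  period_start <- as.Date(if (period_label == "test") "2015-01-01"
                          else "2012-03-01")
  period_days <- if (period_label == "test") 730 else 1035
  admit <- period_start + sample.int(period_days, n, TRUE) - 1L
  los <- pmin(pmax(ceiling(stats::rlnorm(n, params$los_model[["meanlog"]],
                                         params$los_model[["sdlog"]])), 1),
              365)
  lab <- function(m, q1, q3) {
    pars <- .lnorm_match(m, q1, q3)
    round(stats::rlnorm(n, pars[["meanlog"]], pars[["sdlog"]]), 2)
  }
  urea_adm <- lab(6.6, 4.5, 10.6); creat_adm <- lab(77, 63, 114)
  hb_adm <- lab(119, 105, 132); wcc_adm <- lab(7.9, 5.76, 11)
  urea_call <- lab(7, 4.7, 11); creat_call <- lab(78, 63, 120)
  hb_call <- lab(104, 93, 118); wcc_call <- lab(8.12, 6, 11.3)

  # calls per patient: shifted Poisson, guaranteed >= 1
  n_calls <- 1L + stats::rpois(n, params$repeat_call_mean - 1)
  idx <- rep.int(seq_len(n), n_calls)         # patient index per call
  m <- length(idx)

  # trigger category per call (first and repeat calls share the
  # first-call category distribution)
  cat_lab <- sample(names(params$trigger_probs), m, TRUE,
                    params$trigger_probs)
  trig_cell <- cat_lab
  sole <- cat_lab %in% met_vocab$triggers
  other_set <- setdiff(met_vocab$triggers,
                       c("hypotension_sbp_le_90", "gcs_decrease",
                         "hr_le_40", "hr_ge_140", "spo2_le_90", "rr_ge_36"))
  is_ho <- cat_lab == "hypotension_sbp_le_90+other"
  if (any(is_ho)) {
    extra <- sample(other_set, sum(is_ho), TRUE)
    trig_cell[is_ho] <- paste(pmin("hypotension_sbp_le_90", extra),
                              pmax("hypotension_sbp_le_90", extra),
                              sep = ";")
  }
  is_om <- cat_lab == "other_multi"
  if (any(is_om)) {
    non_hypo <- setdiff(met_vocab$triggers, "hypotension_sbp_le_90")
    k <- length(non_hypo)
    i1 <- sample.int(k, sum(is_om), TRUE)
    i2 <- ((i1 + sample.int(k - 1, sum(is_om), TRUE) - 1L) %% k) + 1L
    a <- non_hypo[i1]; b <- non_hypo[i2]
    trig_cell[is_om] <- paste(pmin(a, b), pmax(a, b), sep = ";")
  }
  fixed_multi <- !sole & !is_ho & !is_om
  if (any(fixed_multi)) {
    parts <- strsplit(trig_cell[fixed_multi], "+", fixed = TRUE)
    trig_cell[fixed_multi] <- vapply(parts, function(v)
      paste(sort(v), collapse = ";"), "")
  }
  hypo_call <- grepl("hypotension_sbp_le_90", trig_cell, fixed = TRUE)

  # fluid administration: logistic model at hypotension calls, constant
  # rate otherwise
  b0 <- calibrate_fluid_intercept(
    params$fluid_model,
    p_resp = params$location_probs[["respiratory_ward"]],
    p_card = params$diagnosis_probs[["circulatory_cardiac"]],
    p_hf = params$unit_probs[["heart_failure"]])
  lp <- b0 +
    params$fluid_model[["respiratory_ward"]] *
      (loc[idx] == "respiratory_ward") +
    params$fluid_model[["cardiac_diagnosis"]] *
      (dx[idx] == "circulatory_cardiac") +
    params$fluid_model[["heart_failure_unit"]] *
      (unit[idx] == "heart_failure")
  p_fluid <- ifelse(hypo_call, stats::plogis(lp), params$fluid_other_rate)
  fluid <- stats::runif(m) < p_fluid

  # accompanying interventions (rates conditional on fluid status at
  # hypotension calls follow the published intervention table; rates at
  # other calls are plausibility-only)
  draw <- function(p_hf_fluid, p_hf_no, p_other) {
    p <- ifelse(hypo_call, ifelse(fluid, p_hf_fluid, p_hf_no), p_other)
    stats::runif(m) < p
  }
  ecg <- draw(0.55, 0.29, 0.35)
  blood <- draw(0.44, 0.16, 0.30)
  oxy <- draw(0.09, 0.03, 0.08)
  abg <- draw(0.08, 0.04, 0.05)
  xray <- draw(0.06, 0.04, 0.05)
  medch <- draw(0.11, 0.07, 0.10)
  niv <- draw(0.001, 0.003, 0.01)
  any_active <- fluid | ecg | blood | oxy | abg | xray | medch | niv
  advice <- !any_active & stats::runif(m) < 0.9
  intv_cell <- .join_flags(list(
    abg = abg, advice_only = advice, blood_test = blood, ecg = ecg,
    iv_fluid = fluid, medication_change = medch,
    non_invasive_ventilation = niv, oxygen = oxy, xray = xray), m)

  # call-level outcomes
  icu <- stats::runif(m) < ifelse(hypo_call, 52 / 2459, 311 / 5477)
  pall <- stats::runif(m) < 0.004
  stay <- !icu & stats::runif(m) < 0.98
  out_cell <- .join_flags(list(
    palliative_care_initiated = pall, stayed_on_ward = stay,
    transferred_to_icu = icu), m)

  # timestamps uniform within the stay, sorted per patient
  t_frac <- stats::runif(m)
  ord <- order(idx, t_frac)
  idx <- idx[ord]; trig_cell <- trig_cell[ord]; intv_cell <- intv_cell[ord]
  out_cell <- out_cell[ord]; t_frac <- t_frac[ord]
  ts <- as.POSIXct(admit[idx], tz = "UTC") + round(t_frac * los[idx] * 86400)
  timestamp <- format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

  calls <- data.frame(
    call_id = sprintf("C%07d", seq_len(m)),
    patient_id = pid[idx],
    timestamp = timestamp,
    triggers = trig_cell,
    location = loc[idx],
    interventions = intv_cell,
    outcome_flags = out_cell,
    stringsAsFactors = FALSE
  )

  # episode outcome stratified by the type of the patient's first call
  first_row <- !duplicated(idx)
  first_sole_hypo <- trig_cell[first_row] == "hypotension_sbp_le_90"
  p_die <- ifelse(first_sole_hypo, params$mortality_probs[["hypotension"]],
                  params$mortality_probs[["other"]])
  died <- stats::runif(n) < p_die

  episodes <- data.frame(
    patient_id = pid, age_years = age, gender = gender,
    clinical_unit = unit, diagnosis_group = dx,
    admission_date = format(admit, "%Y-%m-%d"),
    discharge_date = format(admit + los, "%Y-%m-%d"),
    died_in_hospital = died,
    urea_adm = urea_adm, creatinine_adm = creat_adm,
    haemoglobin_adm = hb_adm, wcc_adm = wcc_adm,
    urea_call = urea_call, creatinine_call = creat_call,
    haemoglobin_call = hb_call, wcc_call = wcc_call,
    stringsAsFactors = FALSE
  )
  met_cohort(episodes, calls, period_label = period_label,
             validate = FALSE, .canonical = TRUE)
}
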