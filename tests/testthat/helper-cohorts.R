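# small hand-built cohort used across record-model tests
tiny_cohort <- function() {
  episodes <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    age_years = c(70, 55, 81),
    gender = c("male", "female", "unknown"),
    clinical_unit = c("orthopaedics", "heart_failure", "other_unit"),
    diagnosis_group = c("musculoskeletal", "circulatory_cardiac",
                        "other_dx"),
    admission_date = c("2013-01-01", "2013-02-01", "2013-03-01"),
    discharge_date = c("2013-01-10", "2013-02-05", "2013-03-21"),
    died_in_hospital = c(FALSE, FALSE, TRUE),
    urea_adm = c(6.6, NA, 8.1), creatinine_adm = c(77, 90, NA),
    haemoglobin_adm = c(119, 130, 101), wcc_adm = c(7.9, 10, 12),
    urea_call = c(7, NA, 9), creatinine_call = c(78, 95, NA),
    haemoglobin_call = c(104, 125, 99), wcc_call = c(8.12, 11, 13),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(
    call_id = c("C1", "C2", "C3", "C4", "C5"),
    patient_id = c("P1", "P1", "P2", "P3", "P3"),
    timestamp = c("2013-01-02T10:00:00", "2013-01-04T09:00:00",
                  "2013-02-02T03:30:00", "2013-03-05T12:00:00",
                  "2013-03-06T12:00:00"),
    triggers = c("hypotension_sbp_le_90",
                 "hypotension_sbp_le_90;gcs_decrease",
                 "hypotension_sbp_le_90", "hr_ge_140", "spo2_le_90"),
    location = c("trauma_orthopaedics_ward", "trauma_orthopaedics_ward",
                 "cardiology_cardiothoracic_ward", "other_ward",
                 "other_ward"),
    interventions = c("iv_fluid;ecg", "", "advice_only", "ecg", "oxygen"),
    outcome_flags = c("stayed_on_ward", "stayed_on_ward",
                      "stayed_on_ward", "transferred_to_icu",
                      "stayed_on_ward"),
    stringsAsFactors = FALSE
  )
  met_cohort(episodes, calls)
}
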