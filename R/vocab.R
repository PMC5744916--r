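#' Controlled vocabularies for MET cohort records
#'
#' The record model is purely categorical: the source MET database stored
#' the calling criterion labels, not the underlying vital-sign values, so
#' every field is drawn from a closed vocabulary.
#'
#' @format `met_vocab` is a named list of character vectors:
#' \describe{
#'   \item{triggers}{the 13 MET calling criteria (e.g. systolic blood
#'     pressure at or below 90 mmHg, heart rate at or above 140/min).}
#'   \item{locations}{ward labels for the location of a call.}
#'   \item{clinical_units}{admitting clinical units (parent team).}
#'   \item{diagnosis_groups}{ICD-10 chapter-level primary diagnosis groups.}
#'   \item{interventions}{therapies/investigations delivered at a call.
#'     `advice_only` is mutually exclusive with every other label.}
#'   \item{outcome_flags}{call-level outcomes. `died_at_call` and
#'     `transferred_to_icu` are mutually exclusive.}
#'   \item{genders}{patient gender labels (unknown retained).}
#' }
#' @export
met_vocab <- list(
  triggers = c(
    "hypotension_sbp_le_90", "hr_ge_140", "gcs_decrease", "spo2_le_90",
    "rr_ge_36", "sbp_ge_200", "serious_concern", "hr_le_40", "pain",
    "seizures", "arrest_cpr", "rr_le_6", "uncontrolled_bleeding"
  ),
  locations = c(
    "general_surgery_burns_ward", "trauma_orthopaedics_ward",
    "trauma_neurosurgery_ward", "general_surgery_ward",
    "cardiology_cardiothoracic_ward", "psychiatry_area",
    "respiratory_ward", "other_ward"
  ),
  clinical_units = c(
    "orthopaedics", "breast_endocrine_surgery", "burns",
    "colorectal_surgery", "plastics", "urology", "heart_failure",
    "psychiatry", "general_respiratory", "cystic_fibrosis",
    "lung_transplantation", "neurology", "other_unit"
  ),
  diagnosis_groups = c(
    "circulatory_cardiac", "respiratory", "neurological", "hepatobiliary",
    "ear_nose_mouth_throat", "psychiatric", "musculoskeletal",
    "gastroenterology", "infectious_diseases", "renal_urology",
    "myeloproliferative", "poisonings_toxicology", "endocrine_metabolic",
    "skin_breast", "burns_dx", "haematology", "alcohol_drug", "other_dx"
  ),
  interventions = c(
    "advice_only", "blood_test", "ecg", "oxygen", "abg", "xray",
    "iv_fluid", "medication_change", "non_invasive_ventilation"
  ),
  outcome_flags = c(
    "transferred_to_icu", "died_at_call", "palliative_care_initiated",
    "stayed_on_ward"
  ),
  genders = c("male", "female", "unknown")
)

# Split a semicolon-delimited multi-value cell into a character vector.
split_multi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Join a set of labels into the canonical cell representation (sorted,
# semicolon-delimited) so that written files are byte-stable.
join_multi <- function(labels) {
  vapply(labels, function(v) paste(sort(unique(v)), collapse = ";"), "")
}
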