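#' MET cohort container
#'
#' A `met_cohort` bundles the two tables the MET database exports: one row
#' per hospital admission (`episodes`) and one row per MET activation
#' (`calls`).  Multi-valued fields (`triggers`, `interventions`,
#' `outcome_flags`) are stored as sorted semicolon-delimited cells so the
#' on-disk CSV representation round-trips byte-identically.
#'
#' @param episodes data frame with columns `patient_id`, `age_years`,
#'   `gender`, `clinical_unit`, `diagnosis_group`, `admission_date`,
#'   `discharge_date`, `died_in_hospital`, and the eight lab columns
#'   (`urea_adm`, `creatinine_adm`, `haemoglobin_adm`, `wcc_adm`,
#'   `urea_call`, `creatinine_call`, `haemoglobin_call`, `wcc_call`;
#'   may be `NA`).
#' @param calls data frame with columns `call_id`, `patient_id`,
#'   `timestamp` (ISO-8601), `triggers`, `location`, `interventions`,
#'   `outcome_flags`.
#' @param period_label free-text label, conventionally `"training"` or
#'   `"test"`.
#' @param validate check all invariants (vocabulary closure, non-empty
#'   trigger sets, mutual exclusivities, referential integrity)?
#' @param .canonical internal: caller guarantees multi-value cells are
#'   already sorted and de-duplicated, skipping re-canonicalisation.
#' @return An object of class `met_cohort`: a list with elements
#'   `episodes`, `calls`, `period_label`.  Calls are kept in canonical
#'   order (patient, timestamp, call id).
#' @export
met_cohort <- function(episodes, calls, period_label = "training",
                       validate = TRUE, .canonical = FALSE) {
  episodes <- as.data.frame(episodes, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  ep_cols <- c("patient_id", "age_years", "gender", "clinical_unit",
               "diagnosis_group", "admission_date", "discharge_date",
               "died_in_hospital",
               "urea_adm", "creatinine_adm", "haemoglobin_adm", "wcc_adm",
               "urea_call", "creatinine_call", "haemoglobin_call",
               "wcc_call")
  call_cols <- c("call_id", "patient_id", "timestamp", "triggers",
                 "location", "interventions", "outcome_flags")
  miss_e <- setdiff(ep_cols, names(episodes))
  miss_c <- setdiff(call_cols, names(calls))
  if (length(miss_e) || length(miss_c)) {
    stop("schema error: missing column(s) ",
         paste(c(miss_e, miss_c), collapse = ", "))
  }
  episodes <- episodes[ep_cols]
  calls <- calls[call_cols]
  # canonicalise multi-value cells (sorted, de-duplicated) so that set
  # semantics do not depend on input spelling order
  if (!.canonical) {
    for (col in c("triggers", "interventions", "outcome_flags")) {
      calls[[col]] <- join_multi(split_multi(as.character(calls[[col]])))
    }
  }
  # canonical ordering (also establishes the per-episode time order)
  episodes <- episodes[order(episodes$patient_id), , drop = FALSE]
  calls <- calls[order(calls$patient_id, calls$timestamp, calls$call_id),
                 , drop = FALSE]
  rownames(episodes) <- NULL
  rownames(calls) <- NULL
  obj <- structure(list(episodes = episodes, calls = calls,
                        period_label = period_label),
                   class = "met_cohort")
  if (validate) validate_cohort(obj)
  obj
}

# Check every invariant of the record model; stop at the first violated
# family with offending row numbers (1-based within the canonical order).
validate_cohort <- function(cohort) {
  ep <- cohort$episodes
  ca <- cohort$calls
  bad_rows <- function(ok) which(!ok)
  fail <- function(kind, what, rows) {
    stop(sprintf("%s: %s (row%s %s)", kind, what,
                 if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 10), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(ep$patient_id)) {
    fail("schema error", "duplicate patient_id in episodes",
         which(duplicated(ep$patient_id)))
  }
  chk_vocab <- function(values, vocab, what, where) {
    ok <- values %in% vocab | is.na(values)
    if (!all(ok)) {
      fail("vocabulary error",
           sprintf("unknown %s label(s): %s", what,
                   paste(unique(values[!ok]), collapse = ", ")),
           bad_rows(ok))
    }
  }
  chk_vocab(ep$gender, met_vocab$genders, "gender", "episodes")
  chk_vocab(ep$clinical_unit, met_vocab$clinical_units, "clinical_unit",
            "episodes")
  chk_vocab(ep$diagnosis_group, met_vocab$diagnosis_groups,
            "diagnosis_group", "episodes")
  chk_vocab(ca$location, met_vocab$locations, "location", "calls")
  trig <- split_multi(ca$triggers)
  if (any(lengths(trig) == 0)) {
    fail("schema error", "empty trigger set", bad_rows(lengths(trig) > 0))
  }
  chk_vocab(unlist(trig), met_vocab$triggers, "trigger", "calls")
  intv <- split_multi(ca$interventions)
  chk_vocab(unlist(intv), met_vocab$interventions, "intervention", "calls")
  advice_bad <- vapply(intv, function(v)
    "advice_only" %in% v && length(v) > 1, NA)
  if (any(advice_bad)) {
    fail("schema error",
         "advice_only combined with another intervention",
         bad_rows(!advice_bad))
  }
  fl <- split_multi(ca$outcome_flags)
  chk_vocab(unlist(fl), met_vocab$outcome_flags, "outcome_flag", "calls")
  flag_bad <- vapply(fl, function(v)
    all(c("died_at_call", "transferred_to_icu") %in% v), NA)
  if (any(flag_bad)) {
    fail("schema error",
         "died_at_call and transferred_to_icu both set",
         bad_rows(!flag_bad))
  }
  orphan <- !(ca$patient_id %in% ep$patient_id)
  if (any(orphan)) {
    fail("referential error",
         sprintf("call references absent patient_id: %s",
                 paste(unique(ca$patient_id[orphan]), collapse = ", ")),
         bad_rows(!orphan))
  }
  los_bad <- as.Date(ep$discharge_date) < as.Date(ep$admission_date)
  if (any(los_bad)) {
    fail("schema error", "discharge before admission", bad_rows(!los_bad))
  }
  if (any(ep$age_years < 0, na.rm = TRUE)) {
    fail("schema error", "negative age", bad_rows(!(ep$age_years < 0)))
  }
  invisible(cohort)
}

#' @export
print.met_cohort <- function(x, ...) {
  cat(sprintf("MET cohort (%s period): %d episodes, %d calls\n",
              x$period_label, nrow(x$episodes), nrow(x$calls)))
  npat <- length(unique(x$calls$patient_id))
  cat(sprintf("  patients with >=1 call: %d; calls/patient: %.2f\n",
              npat, if (npat) nrow(x$calls) / npat else 0))
  invisible(x)
}

#' Read a MET cohort from its two-CSV representation
#'
#' @param path directory containing `episodes.csv` and `calls.csv`.
#' @param schema_version dialect version; only `"1"` exists.
#' @param period_label label attached to the returned cohort.
#' @return a validated [met_cohort()].
#' @export
read_cohort <- function(path, schema_version = "1",
                        period_label = "training") {
  if (!identical(schema_version, "1")) {
    stop("schema error: unknown schema_version ", schema_version)
  }
  ep_path <- file.path(path, "episodes.csv")
  ca_path <- file.path(path, "calls.csv")
  if (!file.exists(ep_path) || !file.exists(ca_path)) {
    stop("schema error: expected episodes.csv and calls.csv under ", path)
  }
  ep <- utils::read.csv(ep_path, stringsAsFactors = FALSE, colClasses = c(
    patient_id = "character", age_years = "numeric", gender = "character",
    clinical_unit = "character", diagnosis_group = "character",
    admission_date = "character", discharge_date = "character",
    died_in_hospital = "logical", urea_adm = "numeric",
    creatinine_adm = "numeric", haemoglobin_adm = "numeric",
    wcc_adm = "numeric", urea_call = "numeric",
    creatinine_call = "numeric", haemoglobin_call = "numeric",
    wcc_call = "numeric"))
  ca <- utils::read.csv(ca_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  # empty multi-value cells read back as NA; the canonical form is ""
  for (col in c("interventions", "outcome_flags")) {
    ca[[col]][is.na(ca[[col]])] <- ""
  }
  met_cohort(ep, ca, period_label = period_label)
}

#' Write a MET cohort as two CSV files
#'
#' Rows are emitted in canonical order with a fixed column order, so the
#' same cohort always produces byte-identical files.
#'
#' @param cohort a [met_cohort()].
#' @param path output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "met_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ep_path <- file.path(path, "episodes.csv")
  ca_path <- file.path(path, "calls.csv")
  utils::write.csv(cohort$episodes, ep_path, row.names = FALSE)
  utils::write.csv(cohort$calls, ca_path, row.names = FALSE)
  invisible(c(ep_path, ca_path))
}

#' First MET call per patient
#'
#' Development and impact modelling consider only each patient's first
#' call: the timestamp-minimal one, ties broken by lexically smallest
#' call id.
#'
#' @param cohort a [met_cohort()].
#' @return a data frame with one call row per patient with at least one
#'   call, ordered by `patient_id`.
#' @export
first_calls <- function(cohort) {
  ca <- cohort$calls        # already (patient, timestamp, call_id) sorted
  ca[!duplicated(ca$patient_id), , drop = FALSE]
}

#' Was a call triggered by a single given criterion?
#'
#' `TRUE` iff the call's trigger set is exactly `{criterion}` — the
#' "single calling criterion" reading used throughout the frequency
#' tables; a combination call (e.g. hypotension plus a fall in GCS) is
#' not a sole-criterion call.
#'
#' @param call one row of a cohort's `calls` table (or any list with a
#'   `triggers` cell).
#' @param criterion a trigger label from `met_vocab$triggers`.
#' @return logical scalar.
#' @export
sole_trigger <- function(call, criterion) {
  stopifnot(criterion %in% met_vocab$triggers)
  trig <- split_multi(as.character(call$triggers[1]))[[1]]
  length(trig) == 1 && trig == criterion
}

# Vectorised form over canonical trigger cells.  Because cells are stored
# sorted and de-duplicated, a sole-criterion call is exactly the cell
# equal to the label.
sole_trigger_cell <- function(cells, criterion) {
  cells == criterion
}

# Does the multi-value cell contain the label?
cell_has <- function(cells, label) {
  vapply(split_multi(cells), function(v) label %in% v, NA)
}

#' Per-patient analysis table
#'
#' Flattens a cohort to one row per patient with at least one call:
#' demographics, admission attributes, derived length of stay, call
#' counts, and the attributes of the first call (triggers, location,
#' interventions, outcome flags as canonical multi-value cells).
#'
#' @param cohort a [met_cohort()].
#' @return data frame keyed by `patient_id`.
#' @export
patient_table <- function(cohort) {
  fc <- first_calls(cohort)
  ep <- cohort$episodes
  ep <- ep[match(fc$patient_id, ep$patient_id), , drop = FALSE]
  n_calls <- as.integer(table(cohort$calls$patient_id)[fc$patient_id])
  data.frame(
    patient_id = fc$patient_id,
    age_years = ep$age_years,
    gender = ep$gender,
    clinical_unit = ep$clinical_unit,
    diagnosis_group = ep$diagnosis_group,
    died_in_hospital = ep$died_in_hospital,
    los_days = as.numeric(as.Date(ep$discharge_date) -
                            as.Date(ep$admission_date)),
    urea_adm = ep$urea_adm, creatinine_adm = ep$creatinine_adm,
    haemoglobin_adm = ep$haemoglobin_adm, wcc_adm = ep$wcc_adm,
    urea_call = ep$urea_call, creatinine_call = ep$creatinine_call,
    haemoglobin_call = ep$haemoglobin_call, wcc_call = ep$wcc_call,
    n_calls = n_calls,
    multiple_met = n_calls > 1L,
    first_call_id = fc$call_id,
    first_timestamp = fc$timestamp,
    first_triggers = fc$triggers,
    first_location = fc$location,
    first_interventions = fc$interventions,
    first_outcome_flags = fc$outcome_flags,
    stringsAsFactors = FALSE
  )
}
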