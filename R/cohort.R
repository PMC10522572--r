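# Cohort screening: the four-rule exclusion cascade and incident-case
# identification.

#' Date of first antipsychotic prescription per patient
#'
#' Earliest antipsychotic start date per patient within the enrolment window.
#' Patients without any qualifying prescription are absent from the result.
#' Prescriptions missing the start date anchor on the end date instead (a
#' record with neither date cannot contribute).
#'
#' @param prescriptions Prescription table.
#' @param config A [study_config()].
#' @return Named `Date` vector (names = patient ids).
#' @export
first_antipsychotic_date <- function(prescriptions, config = study_config()) {
  ap <- prescriptions[prescriptions$drug_class == "antipsychotic", , drop = FALSE]
  anchor <- ap$start_date
  anchor[is.na(anchor)] <- ap$end_date[is.na(anchor)]
  keep <- !is.na(anchor) &
    anchor >= config$enrolment_window[1] & anchor <= config$enrolment_window[2]
  ap <- ap[keep, , drop = FALSE]
  anchor <- anchor[keep]
  if (!nrow(ap)) return(stats::setNames(as.Date(character()), character()))
  first <- tapply(as_day(anchor), as.character(ap$patient_id), min)
  stats::setNames(day_to_date(as.integer(first)), names(first))
}

# first lung-cancer diagnosis date per patient (any 162.x code), NA-named map
first_lung_cancer_date <- function(diagnoses, config) {
  lc <- diagnoses[startsWith(as.character(diagnoses$icd9_code),
                             config$lung_cancer_prefix), , drop = FALSE]
  if (!nrow(lc)) return(stats::setNames(as.Date(character()), character()))
  first <- tapply(as_day(lc$diagnosis_date), as.character(lc$patient_id), min)
  stats::setNames(day_to_date(as.integer(first)), names(first))
}

#' Screen the antipsychotic-user cohort
#'
#' Applies the exclusion cascade, in order, to every patient with at least
#' one antipsychotic prescription in the enrolment window:
#' \enumerate{
#'   \item structurally invalid demographics (missing sex or birth date;
#'     an EMPTY death date means alive at database end and is not an
#'     exclusion);
#'   \item incorrect records: death date before the first antipsychotic
#'     prescription;
#'   \item lung-cancer diagnosis before or at the date of the first
#'     antipsychotic prescription;
#'   \item lung-cancer diagnosis before the start of the outcome window
#'     (the screening period removes prevalent cases).
#' }
#' Each patient is counted once, at the first rule that removes them.
#'
#' @param patients,prescriptions,diagnoses The three standard tables.
#' @param config A [study_config()].
#' @return List with `eligible` (patients rows passing all rules, plus
#'   columns `first_ap_date` and `first_lc_date`), and `attrition`
#'   (data frame `rule`, `n_removed`, plus the entry counts).
#' @export
screen_cohort <- function(patients, prescriptions, diagnoses,
                          config = study_config()) {
  first_ap <- first_antipsychotic_date(prescriptions, config)
  pts <- patients[as.character(patients$patient_id) %in% names(first_ap), ,
                  drop = FALSE]
  pts$first_ap_date <- first_ap[as.character(pts$patient_id)]
  first_lc <- first_lung_cancer_date(diagnoses, config)
  pts$first_lc_date <- first_lc[as.character(pts$patient_id)]

  bad_demog <- is.na(pts$birth_date) | is.na(pts$sex) |
    !(pts$sex %in% c("M", "F"))
  bad_record <- !bad_demog &
    !is.na(pts$death_date) & pts$death_date < pts$first_ap_date
  prevalent_at_rx <- !bad_demog & !bad_record &
    !is.na(pts$first_lc_date) & pts$first_lc_date <= pts$first_ap_date
  prevalent_pre_window <- !bad_demog & !bad_record & !prevalent_at_rx &
    !is.na(pts$first_lc_date) & pts$first_lc_date < config$outcome_window[1]

  excluded <- bad_demog | bad_record | prevalent_at_rx | prevalent_pre_window
  attrition <- data.frame(
    rule = c("antipsychotic users in enrolment window",
             "(1) missing age/sex/invalid demographics",
             "(2) death before first antipsychotic prescription",
             "(3) lung cancer on or before first antipsychotic prescription",
             "(4) lung cancer before outcome window",
             "eligible"),
    n = c(nrow(pts), sum(bad_demog), sum(bad_record), sum(prevalent_at_rx),
          sum(prevalent_pre_window), sum(!excluded))
  )
  list(eligible = pts[!excluded, , drop = FALSE], attrition = attrition)
}

#' Identify incident lung-cancer cases
#'
#' One case record per eligible patient whose first lung-cancer diagnosis
#' falls inside the outcome window and whose completed age at that date is at
#' least `config$adult_age`. The index date is the first diagnosis date; the
#' subtype is the ICD-9 code recorded on that date (same-day ties broken by
#' the lowest code).
#'
#' @param eligible The `eligible` element of [screen_cohort()].
#' @param diagnoses Diagnosis table.
#' @param config A [study_config()].
#' @return Data frame with columns `patient_id`, `index_date`,
#'   `age_at_index`, `sex`, `subtype_code`.
#' @export
identify_cases <- function(eligible, diagnoses, config = study_config()) {
  el <- eligible
  has <- !is.na(el$first_lc_date) &
    el$first_lc_date >= config$outcome_window[1] &
    el$first_lc_date <= config$outcome_window[2]
  el <- el[has, , drop = FALSE]
  if (!nrow(el))
    return(data.frame(patient_id = character(), index_date = as.Date(character()),
                      age_at_index = integer(), sex = character(),
                      subtype_code = character()))
  lc <- diagnoses[startsWith(as.character(diagnoses$icd9_code),
                             config$lung_cancer_prefix), , drop = FALSE]
  lc <- lc[order(as.character(lc$patient_id), lc$diagnosis_date,
                 as.character(lc$icd9_code)), , drop = FALSE]
  key <- paste(lc$patient_id, lc$diagnosis_date)
  idx_key <- paste(el$patient_id, el$first_lc_date)
  subtype <- lc$icd9_code[match(idx_key, key)]  # lowest code on the index day
  age <- age_completed(el$birth_date, el$first_lc_date)
  out <- data.frame(patient_id = as.character(el$patient_id),
                    index_date = el$first_lc_date,
                    age_at_index = age,
                    sex = as.character(el$sex),
                    subtype_code = as.character(subtype),
                    stringsAsFactors = FALSE)
  out <- out[out$age_at_index >= config$adult_age, , drop = FALSE]
  out <- out[order(out$index_date, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
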