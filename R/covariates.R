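# Codelist-driven confounder ascertainment over the fixed lookback window
# [covariate_window_start, index_date].

#' Ascertain confounder flags for matched-set members
#'
#' For every (patient, index date) pair, each of the 21 flags is 1 iff the
#' patient has at least one qualifying record dated within
#' `[config$covariate_window_start, index_date]` (upper bound inclusive by
#' default; set `covariate_window_inclusive = FALSE` in the config for a
#' strict pre-index window). Drug-class flags match `prescriptions$drug_class`
#' (anchored on the start date); diagnosis flags match normalized ICD-9 code
#' prefixes.
#'
#' @param members Data frame with columns `patient_id`, `index_date`.
#' @param prescriptions,diagnoses Standard tables.
#' @param config A [study_config()]; `config$codelists` drives the matching.
#' @return `members` with 21 added 0/1 integer columns named as
#'   [covariate_names()].
#' @export
ascertain_covariates <- function(members, prescriptions, diagnoses,
                                 config = study_config()) {
  lists <- config$codelists
  unknown <- setdiff(names(lists), covariate_names())
  if (length(unknown)) stop("unknown covariate flag(s): ",
                            paste(unknown, collapse = ", "))
  w0 <- config$covariate_window_start
  slack <- if (config$covariate_window_inclusive) 0L else 1L
  pid <- as.character(members$patient_id)
  idx <- as_day(members$index_date)
  n <- nrow(members)

  rx_date <- prescriptions$start_date
  rx_date[is.na(rx_date)] <- prescriptions$end_date[is.na(rx_date)]
  rx_ok <- !is.na(rx_date) & rx_date >= w0
  dx_ok <- diagnoses$diagnosis_date >= w0
  dx_code <- as.character(diagnoses$icd9_code)

  for (flag in covariate_names()) {
    cl <- lists[[flag]]
    if (is.null(cl)) { members[[flag]] <- 0L; next }
    if (cl$kind == "drug_class") {
      hit <- rx_ok & prescriptions$drug_class %in% cl$codes
      ev_pid <- as.character(prescriptions$patient_id[hit])
      ev_day <- as_day(rx_date[hit])
    } else {
      pref <- cl$codes
      m <- rep(FALSE, length(dx_code))
      for (p in pref) m <- m | startsWith(dx_code, p)
      hit <- dx_ok & m
      ev_pid <- as.character(diagnoses$patient_id[hit])
      ev_day <- as_day(diagnoses$diagnosis_date[hit])
    }
    if (!length(ev_pid)) { members[[flag]] <- 0L; next }
    first_ev <- tapply(ev_day, ev_pid, min)
    ev <- first_ev[pid]
    members[[flag]] <- as.integer(!is.na(ev) & ev <= idx - slack)
  }
  members
}
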