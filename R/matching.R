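# Incidence-density (risk-set) sampling of controls: up to `ratio` controls
# per case, matched on sex and completed age in years at the case's index
# date, with a per-patient reuse cap. A future case is a valid control for an
# earlier case (its own diagnosis lies after the earlier index date); this is
# what lets the same patient appear as both case and control.

#' Eligible control candidates for one case
#'
#' A screened patient is an eligible control for a case when, at the case's
#' index date, they: are of the same sex; have the same completed age in
#' years; started antipsychotics strictly before the index date; have no
#' lung-cancer diagnosis on or before the index date; are alive (death date
#' empty or after the index date); and are not the case patient.
#'
#' @param case One row of the case table from [identify_cases()].
#' @param pool The `eligible` data frame from [screen_cohort()].
#' @return Character vector of candidate patient ids (unrestricted by the
#'   reuse cap, which only [match_controls()] tracks).
#' @export
eligible_controls <- function(case, pool) {
  idx <- case$index_date
  ok <- pool$sex == case$sex &
    !is.na(pool$first_ap_date) & pool$first_ap_date < idx &
    (is.na(pool$first_lc_date) | pool$first_lc_date > idx) &
    (is.na(pool$death_date) | pool$death_date > idx) &
    as.character(pool$patient_id) != case$patient_id
  ok[ok] <- age_completed(pool$birth_date[ok], idx) == case$age_at_index
  as.character(pool$patient_id[ok])
}

#' Match controls to cases by incidence-density sampling
#'
#' Cases are processed in ascending index date (ties broken by patient id).
#' For each case, up to `config$matching_ratio` controls are drawn uniformly
#' without replacement from the eligible candidates whose use count is still
#' below `config$max_control_reuse`; use counts are then incremented. Cases
#' with zero available controls are dropped and logged. Given identical
#' inputs and `seed`, the output is identical across runs.
#'
#' @param cases Case table from [identify_cases()].
#' @param pool The `eligible` data frame from [screen_cohort()].
#' @param config A [study_config()] (matching ratio and reuse cap).
#' @param seed Integer seed for the sampling stream.
#' @return List with `sets`: data frame (`set_id`, `patient_id`, `role`
#'   in \{"case","control"\}, `index_date`, `sex`, `age_at_index`,
#'   `subtype_code`), and `log`: per-case candidate counts and drop reasons.
#' @export
match_controls <- function(cases, pool, config = study_config(), seed = 1L) {
  if (anyDuplicated(cases$patient_id))
    stop("duplicate case patient ids")
  cases <- cases[order(cases$index_date, cases$patient_id), , drop = FALSE]
  n_cases <- nrow(cases)
  use_count <- new.env(parent = emptyenv())
  uses <- integer(0)

  # pre-split the pool by sex for cheaper per-case filtering
  pool$patient_id <- as.character(pool$patient_id)
  by_sex <- split(pool, pool$sex)

  rng <- set.seed(seed)
  out <- vector("list", n_cases)
  log <- data.frame(patient_id = cases$patient_id,
                    index_date = cases$index_date,
                    n_candidates = integer(n_cases),
                    n_controls = integer(n_cases),
                    dropped = logical(n_cases))
  uses <- stats::setNames(integer(nrow(pool)), pool$patient_id)

  for (i in seq_len(n_cases)) {
    cs <- cases[i, ]
    sub <- by_sex[[cs$sex]]
    cand <- eligible_controls(cs, sub)
    cand <- cand[uses[cand] < config$max_control_reuse]
    cand <- sort(cand)  # deterministic sampling frame
    k <- min(config$matching_ratio, length(cand))
    log$n_candidates[i] <- length(cand)
    log$n_controls[i] <- k
    if (k == 0L) {
      log$dropped[i] <- TRUE
      next
    }
    picked <- if (length(cand) == 1L) cand else sample(cand, k)
    uses[picked] <- uses[picked] + 1L
    out[[i]] <- data.frame(
      set_id = i,
      patient_id = c(cs$patient_id, picked),
      role = c("case", rep("control", k)),
      index_date = cs$index_date,
      sex = cs$sex,
      age_at_index = cs$age_at_index,
      subtype_code = cs$subtype_code,
      stringsAsFactors = FALSE)
  }
  sets <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(sets) <- NULL
  list(sets = sets, log = log)
}
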