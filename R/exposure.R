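# Cumulative drug exposure: duration resolution (3-level imputation
# hierarchy), interval-union day counting, and per-member exposure summaries.
#
# Day-counting convention: a prescription covering [s, e] contributes
# e - s + 1 distinct calendar days (a same-day script is one day of
# exposure). Exposure is truncated at index_date - 1: days on or after the
# index date never count.

#' Build a duration imputer from prescriptions with complete dates
#'
#' Computes the median prescription duration (in days, closed-interval
#' counting) per drug code, plus a global median fallback, using only records
#' where both the start and the end date are present. These medians back the
#' third level of the duration-imputation hierarchy.
#'
#' @param prescriptions Data frame with columns `drug_code`, `start_date`,
#'   `end_date` (`Date`, possibly `NA`).
#' @return An object of class `"duration_imputer"`: list with `per_drug`
#'   (named numeric) and `global` (scalar).
#' @export
duration_imputer <- function(prescriptions) {
  ok <- !is.na(prescriptions$start_date) & !is.na(prescriptions$end_date)
  dur <- as_day(prescriptions$end_date[ok]) - as_day(prescriptions$start_date[ok]) + 1L
  drug <- as.character(prescriptions$drug_code[ok])
  per_drug <- if (length(dur)) vapply(split(dur, drug), stats::median, 0) else numeric(0)
  glob <- if (length(dur)) stats::median(dur) else 1
  structure(list(per_drug = per_drug, global = as.numeric(glob)),
            class = "duration_imputer")
}

#' Resolve prescription records to day intervals
#'
#' Applies the three-level duration hierarchy to every record:
#' \enumerate{
#'   \item both dates present: the interval is used as recorded;
#'   \item one date missing but dosage, frequency and quantity all present
#'     (and dosage x frequency > 0): duration =
#'     `ceiling(quantity / (dosage * frequency_per_day))` days, anchored at
#'     the known date;
#'   \item otherwise: duration = the drug's median complete-record duration
#'     (global median if the drug has none), anchored at the known date.
#' }
#' Records with neither date carry no anchor and are dropped with a warning.
#'
#' @param prescriptions Data frame with columns `patient_id`, `drug_code`,
#'   `start_date`, `end_date`, `dosage`, `frequency_per_day`, `quantity`.
#' @param imputer A [duration_imputer()].
#' @return The input rows that could be resolved, with integer day columns
#'   `start`, `end` (`end >= start`) and a column `resolution_level` in 1:3.
#' @export
resolve_durations <- function(prescriptions, imputer) {
  p <- prescriptions
  s <- as_day(p$start_date)
  e <- as_day(p$end_date)
  anchored <- !(is.na(s) & is.na(e))
  if (any(!anchored)) {
    warning(sum(!anchored), " prescription record(s) with neither date dropped")
    p <- p[anchored, , drop = FALSE]
    s <- s[anchored]; e <- e[anchored]
  }
  n <- nrow(p)
  level <- integer(n)
  dur <- numeric(n)

  lvl1 <- !is.na(s) & !is.na(e)
  if (any(lvl1 & e < s, na.rm = TRUE))
    stop("prescription with end_date before start_date")
  level[lvl1] <- 1L

  dq <- p$dosage; fq <- p$frequency_per_day; qt <- p$quantity
  daily <- ifelse(!is.na(dq) & !is.na(fq), dq * fq, NA_real_)
  lvl2 <- !lvl1 & !is.na(daily) & daily > 0 & !is.na(qt)
  dur[lvl2] <- ceiling(qt[lvl2] / daily[lvl2])
  level[lvl2] <- 2L

  lvl3 <- !lvl1 & !lvl2
  if (any(lvl3)) {
    med <- imputer$per_drug[as.character(p$drug_code[lvl3])]
    med[is.na(med)] <- imputer$global
    dur[lvl3] <- med
    level[lvl3] <- 3L
  }
  dur <- pmax(1, round(dur))

  imp <- level > 1L
  miss_start <- imp & is.na(s)
  s[miss_start] <- e[miss_start] - dur[miss_start] + 1L
  miss_end <- imp & is.na(e)
  e[miss_end] <- s[miss_end] + dur[miss_end] - 1L

  p$start <- as.integer(s)
  p$end <- as.integer(e)
  p$resolution_level <- level
  p
}

#' Count distinct calendar days covered by a set of intervals
#'
#' Sort-and-sweep union count: the number of days covered by at least one
#' interval, after truncating every interval at `index_day - 1` (exposure must
#' strictly precede the index date). Overlapping prescriptions therefore
#' contribute each calendar day once.
#'
#' @param start,end Integer day numbers (closed intervals, `end >= start`).
#' @param index_day Integer day number of the index date, or `NULL` for no
#'   truncation.
#' @return Non-negative integer day count.
#' @export
union_days <- function(start, end, index_day = NULL) {
  if (!is.null(index_day)) {
    end <- pmin(end, index_day - 1L)
    keep <- start <= end
    start <- start[keep]; end <- end[keep]
  }
  if (!length(start)) return(0L)
  o <- order(start, end)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  # sweep: extend the current run or open a new one
  run_end <- cummax(end)
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)] + 1L)
  grp <- cumsum(new_run)
  first <- start[new_run]
  last <- vapply(split(run_end, grp), max, 0L)
  sum(last - first + 1L)
}

# Merge closed integer intervals into disjoint runs; returns a data.frame
# (start, end) sorted. Adjacent intervals (gap 0) are merged.
merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  run_end <- cummax(end)
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)] + 1L)
  grp <- cumsum(new_run)
  data.frame(start = start[new_run],
             end = as.integer(vapply(split(run_end, grp), max, 0L)))
}

#' Cumulative exposure days for one drug group
#'
#' Union-day count restricted to one group of prescriptions (e.g. flupentixol
#' only). By default overlapping same-drug prescriptions are also counted
#' once; set `union = FALSE` to sum raw (truncated) durations instead.
#'
#' @inheritParams union_days
#' @param union Logical; count each covered day once (default) or sum
#'   durations.
#' @export
drug_days <- function(start, end, index_day = NULL, union = TRUE) {
  if (union) return(union_days(start, end, index_day))
  if (!is.null(index_day)) {
    end <- pmin(end, index_day - 1L)
    keep <- start <= end
    start <- start[keep]; end <- end[keep]
  }
  if (!length(start)) return(0L)
  sum(end - start + 1L)
}

# category index 1..3 from day counts and cut-points {365, 1825}
exposure_category <- function(days, cut_points) {
  findInterval(days, c(cut_points[1] + 1L, cut_points[2] + 1L)) + 1L
}

category_labels <- function(cut_points, zero_based = FALSE) {
  lo <- if (zero_based) "0" else "1"
  c(paste0(lo, "-", cut_points[1]),
    paste0(cut_points[1] + 1L, "-", cut_points[2]),
    paste0(cut_points[2] + 1L, "+"))
}

#' Summarize cumulative antipsychotic exposure before a set of index dates
#'
#' For each (patient, index date) pair, computes cumulative exposure days
#' before the index date for (a) any antipsychotic (interval union across all
#' antipsychotic prescriptions), (b) flupentixol, and (c) antipsychotics other
#' than flupentixol, and assigns each to its exposure category.
#'
#' Members of a matched set must have at least one day of any-antipsychotic
#' exposure before their index date; a zero-day member violates the design's
#' inclusion rule and raises an error.
#'
#' @param members Data frame with columns `patient_id` and `index_date`.
#' @param prescriptions Prescription table (all drug classes; only rows with
#'   `drug_class == "antipsychotic"` contribute).
#' @param config A [study_config()].
#' @param imputer Optional [duration_imputer()]; built from the antipsychotic
#'   prescriptions if omitted.
#' @return `members` with integer columns `days_any`, `days_flupentixol`,
#'   `days_other` and integer category columns `cat_any`, `cat_flupentixol`,
#'   `cat_other` (1 = reference).
#' @export
summarize_exposure <- function(members, prescriptions, config, imputer = NULL) {
  ap <- prescriptions[prescriptions$drug_class == "antipsychotic", , drop = FALSE]
  if (is.null(imputer)) imputer <- duration_imputer(ap)
  res <- resolve_durations(ap, imputer)
  is_flu <- res$drug_code == config$flupentixol_code
  by_pat <- split(seq_len(nrow(res)), as.character(res$patient_id))

  n <- nrow(members)
  idx <- as_day(members$index_date)
  pid <- as.character(members$patient_id)
  d_any <- d_flu <- d_oth <- integer(n)
  for (i in seq_len(n)) {
    rows <- by_pat[[pid[i]]]
    if (is.null(rows)) rows <- integer(0)
    s <- res$start[rows]; e <- res$end[rows]; f <- is_flu[rows]
    d_any[i] <- union_days(s, e, idx[i])
    d_flu[i] <- drug_days(s[f], e[f], idx[i], union = config$within_drug_union)
    d_oth[i] <- drug_days(s[!f], e[!f], idx[i], union = config$within_drug_union)
  }
  if (any(d_any == 0L))
    stop("member(s) with zero days of antipsychotic exposure before the index date: ",
         paste(utils::head(pid[d_any == 0L]), collapse = ", "))
  members$days_any <- d_any
  members$days_flupentixol <- d_flu
  members$days_other <- d_oth
  cp <- config$cut_points
  members$cat_any <- exposure_category(d_any, cp)
  members$cat_flupentixol <- exposure_category(d_flu, cp)
  members$cat_other <- exposure_category(d_oth, cp)
  members
}
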