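# Orchestration: assemble the analysis bundle (screen -> identify cases ->
# match -> exposure -> covariates), build the two regression designs, and run
# the primary, sex-stratified, leave-one-out and sensitivity analyses.

#' Assemble the full nested case-control analysis bundle
#'
#' Runs the whole data pipeline on the three standard tables: screening
#' cascade, incident-case identification, incidence-density matching,
#' cumulative-exposure summaries and confounder ascertainment.
#'
#' @param tables List with `patients`, `prescriptions`, `diagnoses` (e.g.
#'   from [sim_ehr()] or [read_ehr_tables()]).
#' @param config A [study_config()].
#' @param seed Seed for the matching sampler.
#' @return List of class `"ncc_bundle"`: `members` (one row per matched-set
#'   member with exposure and covariate columns), `cases`, `screen`
#'   (attrition), `matching_log`, `config`, `seed`, `tables`.
#' @export
ncc_data <- function(tables, config = study_config(), seed = 1L) {
  scr <- screen_cohort(tables$patients, tables$prescriptions,
                       tables$diagnoses, config)
  cases <- identify_cases(scr$eligible, tables$diagnoses, config)
  if (nrow(cases) == 0L) stop("no eligible incident cases", call. = FALSE)
  mt <- match_controls(cases, scr$eligible, config, seed = seed)
  if (is.null(mt$sets) || nrow(mt$sets) == 0L)
    stop("no matched sets could be formed", call. = FALSE)
  members <- summarize_exposure(mt$sets, tables$prescriptions, config)
  members <- ascertain_covariates(members, tables$prescriptions,
                                  tables$diagnoses, config)
  structure(list(members = members, cases = cases, screen = scr$attrition,
                 matching_log = mt$log, config = config, seed = seed,
                 tables = tables),
            class = "ncc_bundle")
}

#' Build the design matrix for one of the two regression analyses
#'
#' `analysis_one` regresses case status on two flupentixol exposure-category
#' indicators (reference 0-365 days) plus two indicators for cumulative use
#' of antipsychotics other than flupentixol (reference 0-365 days) plus the
#' 21 confounders (25 columns). `analysis_two` uses two any-antipsychotic
#' category indicators (reference 1-365 days) plus the 21 confounders
#' (23 columns).
#'
#' @param members Member table from [ncc_data()] (or any data frame with the
#'   exposure category and covariate columns).
#' @param model `"analysis_one"` or `"analysis_two"`.
#' @return List with `X` (numeric matrix), `case` (logical), `set` (set ids),
#'   `model`.
#' @export
build_design <- function(members, model = c("analysis_one", "analysis_two")) {
  model <- match.arg(model)
  need <- c("cat_any", "cat_flupentixol", "cat_other", covariate_names())
  miss <- setdiff(need, names(members))
  if (length(miss)) stop("members lack required columns: ",
                         paste(miss, collapse = ", "))
  ind <- function(cat, prefix) {
    m <- cbind(as.integer(cat == 2L), as.integer(cat == 3L))
    colnames(m) <- paste0(prefix, c("_366_1825", "_1826plus"))
    m
  }
  Z <- as.matrix(members[, covariate_names(), drop = FALSE])
  X <- if (model == "analysis_one") {
    cbind(ind(members$cat_flupentixol, "flupentixol"),
          ind(members$cat_other, "other_ap"), Z)
  } else {
    cbind(ind(members$cat_any, "any_ap"), Z)
  }
  storage.mode(X) <- "double"
  list(X = X, case = members$role == "case", set = members$set_id,
       model = model)
}

# fit one analysis on a member table, returning the OR table + diagnostics;
# sets that lost their case or all controls are dropped first (logged)
fit_members <- function(members, model, label = model) {
  members <- prune_sets(members)
  if (is.null(members) || !nrow(members))
    return(list(label = label, fit = NULL, table = empty_or_table(label),
                n_sets = 0L, n_informative = 0L))
  d <- build_design(members, model)
  # drop aliased columns: only within-set contrasts identify the conditional
  # likelihood, so rank is assessed on the set-centered design (this also
  # removes columns constant within every set, e.g. a covariate absent from
  # a stratum)
  ctr <- rowsum(d$X, d$set, reorder = FALSE)
  sizes <- as.vector(table(factor(d$set, levels = unique(d$set))))
  Xc <- d$X - (ctr / sizes)[match(d$set, unique(d$set)), , drop = FALSE]
  qr_d <- qr(Xc)
  keep <- sort(qr_d$pivot[seq_len(qr_d$rank)])
  fit <- cclogit_fit(d$X[, keep, drop = FALSE], d$case, d$set)
  tab <- wald_table(fit)
  tab <- cbind(analysis = label, tab, n_sets = fit$n_sets,
               n_informative = fit$n_informative)
  list(label = label, fit = fit, table = tab,
       n_sets = fit$n_sets, n_informative = fit$n_informative,
       dropped_terms = setdiff(colnames(d$X), colnames(d$X)[keep]))
}

empty_or_table <- function(label) {
  data.frame(analysis = character(), term = character(), beta = numeric(),
             se = numeric(), OR = numeric(), lo95 = numeric(),
             hi95 = numeric(), p = numeric(), significant = logical(),
             n_sets = integer(), n_informative = integer())
}

# keep only sets that still have exactly one case and >=1 control
prune_sets <- function(members) {
  if (is.null(members) || !nrow(members)) return(members)
  has_case <- tapply(members$role == "case", members$set_id, any)
  has_ctrl <- tapply(members$role == "control", members$set_id, any)
  ok_sets <- names(has_case)[has_case & has_ctrl]
  members[as.character(members$set_id) %in% ok_sets, , drop = FALSE]
}

#' Primary analyses: flupentixol (analysis one) and any antipsychotic
#' (analysis two)
#'
#' @param bundle An [ncc_data()] bundle.
#' @return List with elements `analysis_one`, `analysis_two`, each holding
#'   the `cclogit` fit and its Wald OR table.
#' @export
run_primary <- function(bundle) {
  list(analysis_one = fit_members(bundle$members, "analysis_one"),
       analysis_two = fit_members(bundle$members, "analysis_two"))
}

#' Sex-stratified subgroup analyses
#'
#' Matched sets are sex-homogeneous, so stratification keeps whole sets whose
#' case has the given sex and refits both analyses per stratum.
#'
#' @param bundle An [ncc_data()] bundle.
#' @return Nested list: `male`/`female`, each with `analysis_one`,
#'   `analysis_two`.
#' @export
run_sex_strata <- function(bundle) {
  out <- lapply(c(male = "M", female = "F"), function(sx) {
    mem <- bundle$members[bundle$members$sex == sx, , drop = FALSE]
    list(analysis_one = fit_members(mem, "analysis_one",
                                    paste0("analysis_one_", sx)),
         analysis_two = fit_members(mem, "analysis_two",
                                    paste0("analysis_two_", sx)))
  })
  out
}

#' Leave-one-out outcome-subtype analyses
#'
#' For each of the seven ICD-9 lung-cancer subtype codes, drops every matched
#' set whose case has that subtype (controls exist only relative to their
#' case) and refits the requested analyses.
#'
#' @param bundle An [ncc_data()] bundle.
#' @param models Which analyses to refit.
#' @return Named list over subtype codes; each element a list over models.
#' @export
run_leave_one_out <- function(bundle,
                              models = c("analysis_one", "analysis_two")) {
  mem <- bundle$members
  case_subtype <- mem$subtype_code[mem$role == "case"]
  names(case_subtype) <- mem$set_id[mem$role == "case"]
  out <- lapply(lung_cancer_subtypes(), function(code) {
    drop_sets <- names(case_subtype)[case_subtype == code]
    sub <- mem[!(as.character(mem$set_id) %in% drop_sets), , drop = FALSE]
    fits <- lapply(models, function(m)
      if (nrow(sub)) fit_members(sub, m, paste0(m, "_excl_", code))
      else list(label = paste0(m, "_excl_", code), fit = NULL,
                table = empty_or_table(m)))
    names(fits) <- models
    c(fits, list(n_sets_excluded = length(drop_sets)))
  })
  names(out) <- lung_cancer_subtypes()
  out
}

#' Sensitivity analysis: exclude prior users of specific antipsychotics
#'
#' Removes every member (case or control) with at least one prescription of
#' any listed drug strictly before their set's index date; sets that lose
#' their case or all controls are dropped; both analyses are refitted.
#'
#' @param bundle An [ncc_data()] bundle.
#' @param drugs Character vector of drug codes (default the ten agents with
#'   previously reported lung-cancer risk reduction).
#' @return List with `analysis_one`, `analysis_two`, `n_members_removed`.
#' @export
run_sensitivity_exclude_drugs <- function(bundle,
                                          drugs = sensitivity_drug_list()) {
  rx <- bundle$tables$prescriptions
  rx <- rx[rx$drug_code %in% drugs, , drop = FALSE]
  anchor <- rx$start_date
  anchor[is.na(anchor)] <- rx$end_date[is.na(anchor)]
  ok <- !is.na(anchor)
  first_use <- tapply(as_day(anchor[ok]), as.character(rx$patient_id[ok]), min)
  mem <- bundle$members
  fu <- first_use[as.character(mem$patient_id)]
  remove <- !is.na(fu) & fu < as_day(mem$index_date)
  kept <- mem[!remove, , drop = FALSE]
  list(analysis_one = fit_members(kept, "analysis_one", "sens1_analysis_one"),
       analysis_two = fit_members(kept, "analysis_two", "sens1_analysis_two"),
       n_members_removed = sum(remove))
}

#' Sensitivity analysis: unlimited control reuse
#'
#' Re-runs the matching stage with no per-patient reuse cap (same seed), then
#' the full downstream pipeline and both analyses.
#'
#' @param bundle An [ncc_data()] bundle.
#' @return A new bundle's primary results plus the re-matched bundle itself.
#' @export
run_sensitivity_unlimited_reuse <- function(bundle) {
  cfg <- bundle$config
  cfg$max_control_reuse <- Inf
  b2 <- ncc_data(bundle$tables, cfg, seed = bundle$seed)
  c(run_primary(b2), list(bundle = b2))
}

## ---- descriptive output ---------------------------------------------------

# percentage as printed in the descriptive tables: 2-decimal rounding
count_pct <- function(n, total) round(100 * n / total, 2)

#' Descriptive characteristics of cases and controls
#'
#' Counts and percentages by role for sex, age bands (18-24, 25-44, 45-64,
#' 65-84, 85+), mean (SD) age, and each co-medication / comorbidity flag.
#'
#' @param members Member table from [ncc_data()].
#' @return Data frame with columns `variable`, `level`, `case_n`, `case_pct`,
#'   `control_n`, `control_pct` (percentages rounded to 2 decimals; the mean
#'   age row reports mean and SD instead of count and percentage).
#' @export
descriptive_table <- function(members) {
  is_case <- members$role == "case"
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  row <- function(variable, level, flag) {
    data.frame(variable = variable, level = level,
               case_n = sum(flag & is_case),
               case_pct = count_pct(sum(flag & is_case), n_case),
               control_n = sum(flag & !is_case),
               control_pct = count_pct(sum(flag & !is_case), n_ctrl))
  }
  age_band <- cut(members$age_at_index, c(18, 25, 45, 65, 85, Inf),
                  right = FALSE, labels = c("18-24", "25-44", "45-64",
                                            "65-84", "85+"))
  out <- rbind(
    row("sex", "F", members$sex == "F"),
    row("sex", "M", members$sex == "M"),
    do.call(rbind, lapply(levels(age_band), function(b)
      row("age", b, !is.na(age_band) & age_band == b))),
    data.frame(variable = "age", level = "mean (SD)",
               case_n = round(mean(members$age_at_index[is_case]), 2),
               case_pct = round(stats::sd(members$age_at_index[is_case]), 2),
               control_n = round(mean(members$age_at_index[!is_case]), 2),
               control_pct = round(stats::sd(members$age_at_index[!is_case]), 2)),
    do.call(rbind, lapply(covariate_names(), function(nm)
      row(nm, "1", members[[nm]] == 1L)))
  )
  rownames(out) <- NULL
  out
}

#' Exposure-category prevalence among cases and controls
#'
#' The category shares feeding the forest-plot style output: for flupentixol
#' (0-365 reference) and any antipsychotic (1-365 reference) exposure, the
#' count and 2-decimal percentage of cases and controls per category.
#'
#' @param members Member table from [ncc_data()].
#' @param cut_points Integer cut-points (days).
#' @return Data frame with `exposure`, `category`, `case_n`, `case_pct`,
#'   `control_n`, `control_pct`.
#' @export
exposure_prevalence <- function(members, cut_points = c(365L, 1825L)) {
  is_case <- members$role == "case"
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  one <- function(exposure, cat, labels) {
    do.call(rbind, lapply(1:3, function(l)
      data.frame(exposure = exposure, category = labels[l],
                 case_n = sum(is_case & cat == l),
                 case_pct = count_pct(sum(is_case & cat == l), n_case),
                 control_n = sum(!is_case & cat == l),
                 control_pct = count_pct(sum(!is_case & cat == l), n_ctrl))))
  }
  out <- rbind(
    one("flupentixol", members$cat_flupentixol,
        category_labels(cut_points, zero_based = TRUE)),
    one("any_antipsychotic", members$cat_any,
        category_labels(cut_points, zero_based = FALSE))
  )
  rownames(out) <- NULL
  out
}
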