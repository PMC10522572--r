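# Study configuration: windows, codelists, cut-points, matching policy.

#' Names of the adjusted confounder flags, in their fixed model order
#'
#' Four co-medication flags followed by seventeen diagnosis flags. This
#' ordering is used everywhere a covariate vector or design matrix is built.
#'
#' @return Character vector of length 21.
#' @export
covariate_names <- function() {
  c("nsaids", "statins", "aspirin", "metformin",
    "tobacco_use", "diabetes", "copd", "hypertension", "hyperlipidemia",
    "cirrhosis", "ckd", "peptic_ulcer", "pneumonia", "schizophrenia",
    "depressive_disorders", "anxiety_disorders", "bipolar_disorders",
    "personality_disorders", "delusional_disorders",
    "other_nonorganic_psychoses", "dementia")
}

#' Default confounder codelists (synthetic placeholders)
#'
#' Maps each confounder flag either to a drug class (for the four
#' co-medication flags) or to a set of ICD-9 code prefixes (for the seventeen
#' diagnosis flags). These defaults are written to line up with the codes the
#' synthetic generator emits; they are NOT an authoritative clinical codelist
#' and real-data users must supply their own via `study_config(codelists=)`.
#'
#' @return Named list; each element is a list with fields `kind`
#'   (`"drug_class"` or `"icd9_prefix"`) and `codes`.
#' @export
default_codelists <- function() {
  drug <- function(cls) list(kind = "drug_class", codes = cls)
  icd <- function(...) list(kind = "icd9_prefix", codes = c(...))
  list(
    nsaids = drug("nsaid"),
    statins = drug("statin"),
    aspirin = drug("aspirin"),
    metformin = drug("metformin"),
    tobacco_use = icd("305.1"),
    diabetes = icd("250"),
    copd = icd("491", "492", "496"),
    hypertension = icd("401"),
    hyperlipidemia = icd("272"),
    cirrhosis = icd("571"),
    ckd = icd("585"),
    peptic_ulcer = icd("533"),
    pneumonia = icd("486"),
    schizophrenia = icd("295"),
    depressive_disorders = icd("296.2", "296.3", "311"),
    anxiety_disorders = icd("300.0"),
    bipolar_disorders = icd("296.4", "296.5", "296.6", "296.7"),
    personality_disorders = icd("301"),
    delusional_disorders = icd("297"),
    other_nonorganic_psychoses = icd("298"),
    dementia = icd("290")
  )
}

#' Antipsychotic agents whose prior users are removed in sensitivity analysis
#'
#' The ten agents with previously reported lung-cancer risk reduction; members
#' with any pre-index prescription of these are excluded in the first
#' sensitivity analysis.
#'
#' @return Character vector of drug codes.
#' @export
sensitivity_drug_list <- function() {
  c("risperidone", "pimozide", "aripiprazole", "olanzapine", "lurasidone",
    "brexpiprazole", "trifluoperazine", "clozapine", "chlorpromazine",
    "haloperidol")
}

#' Study configuration
#'
#' Bundles every window, cut-point, codelist and matching policy the pipeline
#' uses. Defaults reproduce the published design: enrolment of antipsychotic
#' initiators 2001-01-01 to 2022-08-31, the years 2001-2002 as a screening
#' period for prevalent lung cancer, outcome window 2003-01-01 to 2022-08-31,
#' exposure categories cut at 365 and 1825 days, 10 controls per case with a
#' reuse cap of 4.
#'
#' @param outcome_window Length-2 `Date` vector: first and last admissible
#'   index dates.
#' @param enrolment_window Length-2 `Date` vector for the first antipsychotic
#'   prescription.
#' @param covariate_window_start `Date`: lower bound of confounder
#'   ascertainment (clinical information before this date is unavailable).
#' @param lung_cancer_prefix ICD-9 prefix identifying the outcome (all 162.x).
#' @param adult_age Minimum age at index, in completed years.
#' @param cut_points Increasing integer cut-points (days) separating the three
#'   cumulative-exposure categories.
#' @param matching_ratio Maximum number of controls per case.
#' @param max_control_reuse Maximum number of distinct cases a patient may
#'   serve as control for; `Inf` for the unlimited-reuse sensitivity analysis.
#' @param codelists Confounder codelists, see [default_codelists()].
#' @param flupentixol_code Drug code identifying flupentixol prescriptions.
#' @param within_drug_union Count overlapping same-drug prescriptions once
#'   (`TRUE`, default) or sum raw durations (`FALSE`).
#' @param covariate_window_inclusive Include the index date itself in the
#'   confounder ascertainment window (default `TRUE`).
#' @return A list of class `"ncc_config"`.
#' @export
study_config <- function(outcome_window = as.Date(c("2003-01-01", "2022-08-31")),
                         enrolment_window = as.Date(c("2001-01-01", "2022-08-31")),
                         covariate_window_start = as.Date("2001-01-01"),
                         lung_cancer_prefix = "162",
                         adult_age = 18L,
                         cut_points = c(365L, 1825L),
                         matching_ratio = 10L,
                         max_control_reuse = 4,
                         codelists = default_codelists(),
                         flupentixol_code = "flupentixol",
                         within_drug_union = TRUE,
                         covariate_window_inclusive = TRUE) {
  stopifnot(length(cut_points) == 2L, diff(cut_points) > 0,
            outcome_window[1] <= outcome_window[2],
            enrolment_window[1] <= enrolment_window[2],
            matching_ratio >= 1L, max_control_reuse >= 1)
  unknown <- setdiff(names(codelists), covariate_names())
  if (length(unknown))
    stop("unknown covariate flag(s) in codelists: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(
    outcome_window = outcome_window,
    enrolment_window = enrolment_window,
    covariate_window_start = covariate_window_start,
    lung_cancer_prefix = lung_cancer_prefix,
    adult_age = as.integer(adult_age),
    cut_points = as.integer(cut_points),
    matching_ratio = as.integer(matching_ratio),
    max_control_reuse = max_control_reuse,
    codelists = codelists,
    flupentixol_code = flupentixol_code,
    within_drug_union = isTRUE(within_drug_union),
    covariate_window_inclusive = isTRUE(covariate_window_inclusive)
  ), class = "ncc_config")
}

# The seven ICD-9 lung-cancer subtype codes used for leave-one-out analyses.
#' @export
#' @rdname study_config
lung_cancer_subtypes <- function() {
  c("162.0", "162.2", "162.3", "162.4", "162.5", "162.8", "162.9")
}
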