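# Synthetic EHR generator. Emulates a territory-wide dispensing/diagnosis
# database restricted to antipsychotic initiators: per-patient prescription
# episodes (overlapping and gapped, with a small completely-at-random
# missing-end-date fraction), binary comorbidity/co-medication events, and a
# lung-cancer outcome simulated on a 30-day discrete-time logistic hazard
# whose log-odds depend on the CURRENT cumulative any-antipsychotic exposure
# category. Because the true exposure effect is configured, the full
# screen -> match -> expose -> fit pipeline can be checked for parameter
# recovery without any external data.

other_antipsychotics <- function() {
  c(sensitivity_drug_list(),
    "quetiapine", "amisulpride", "sulpiride", "paliperidone", "zuclopenthixol")
}

default_covariate_prevalences <- function() {
  stats::setNames(c(
    0.49, 0.28, 0.39, 0.19,
    0.008, 0.20, 0.095, 0.36, 0.10, 0.017, 0.028, 0.007, 0.19,
    0.20, 0.13, 0.034, 0.032, 0.012, 0.048, 0.083, 0.28
  ), covariate_names())
}

default_covariate_log_ors <- function() {
  v <- stats::setNames(numeric(21), covariate_names())
  v[c("nsaids", "tobacco_use", "copd", "pneumonia", "dementia")] <-
    log(c(1.2, 1.5, 1.8, 1.6, 0.8))
  v
}

#' Configuration for the synthetic EHR generator
#'
#' Defaults describe the emulated cohort: antipsychotic initiators with a
#' first prescription between 2001-01-01 and 2022-08-31, a negative-binomial
#' number of dispensing episodes per patient with lognormal episode lengths
#' and exponential gaps (a configurable fraction of episodes overlapping the
#' previous one, to exercise union counting), about 2 percent of episodes
#' missing the end date, and a discrete-time (30-day) logistic lung-cancer
#' hazard with configured log-odds effects for the 366-1825 and 1826+ day
#' cumulative-exposure categories. Death is a competing event on the same
#' grid.
#'
#' @param n_patients Number of patients.
#' @param prob_male Probability of male sex.
#' @param birth_year_range Inclusive calendar-year range of birth dates.
#' @param first_rx_window Window for the first antipsychotic prescription.
#' @param episodes_mean,episodes_dispersion Negative-binomial mean and size
#'   for the number of episodes beyond the first.
#' @param episode_log_mean,episode_log_sd Lognormal parameters for episode
#'   length in days.
#' @param gap_mean_days Mean of the exponential gap between episodes.
#' @param overlap_prob Probability a new episode starts before the previous
#'   one ends.
#' @param prob_flupentixol_user Fraction of patients who ever receive
#'   flupentixol.
#' @param flup_episode_prob Within flupentixol users, probability an episode
#'   is flupentixol.
#' @param missing_end_date_rate Fraction of antipsychotic episodes whose end
#'   date is removed (completely at random).
#' @param missing_keep_fields_prob Among missing-end-date episodes, the
#'   fraction that keep dosage/frequency/quantity (supporting arithmetic
#'   duration imputation); the rest keep only the drug code.
#' @param covariate_prevalences Named probabilities for the 21 confounder
#'   flags.
#' @param covariate_log_ors Named log-odds effects of the confounders on the
#'   outcome hazard.
#' @param baseline_hazard_logit Baseline log-odds of lung cancer per 30-day
#'   step (reference exposure category).
#' @param true_log_or_cat2,true_log_or_cat3 Log-odds effects of the 366-1825
#'   and 1826+ day cumulative any-antipsychotic categories.
#' @param death_hazard_per_step Per-step death probability (competing event).
#' @param subtype_weights Sampling weights for the seven ICD-9 lung-cancer
#'   subtype codes.
#' @param seed Integer seed; fully determines the generated tables.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 20000L,
                       prob_male = 0.5,
                       birth_year_range = c(1920L, 1985L),
                       first_rx_window = as.Date(c("2001-01-01", "2022-08-31")),
                       episodes_mean = 35,
                       episodes_dispersion = 0.25,
                       episode_log_mean = log(75),
                       episode_log_sd = 1.2,
                       gap_mean_days = 25,
                       overlap_prob = 0.2,
                       prob_flupentixol_user = 0.10,
                       flup_episode_prob = 0.7,
                       missing_end_date_rate = 0.02,
                       missing_keep_fields_prob = 0.5,
                       covariate_prevalences = default_covariate_prevalences(),
                       covariate_log_ors = default_covariate_log_ors(),
                       baseline_hazard_logit = -8.3,
                       true_log_or_cat2 = log(0.5),
                       true_log_or_cat3 = log(0.6),
                       death_hazard_per_step = 0.003,
                       subtype_weights = c("162.0" = 0.01, "162.2" = 0.06,
                                           "162.3" = 0.35, "162.4" = 0.05,
                                           "162.5" = 0.15, "162.8" = 0.03,
                                           "162.9" = 0.35),
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("'n_patients' must be a positive integer", call. = FALSE)
  for (nm in c("prob_male", "overlap_prob", "prob_flupentixol_user",
               "flup_episode_prob", "missing_end_date_rate",
               "missing_keep_fields_prob", "death_hazard_per_step"))
    stopifnot_prob(get(nm), nm)
  stopifnot_prob(covariate_prevalences, "covariate_prevalences")
  stopifnot(length(first_rx_window) == 2L,
            first_rx_window[1] <= first_rx_window[2],
            episodes_mean > 0, episodes_dispersion > 0, gap_mean_days > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic EHR population
#'
#' Draws the full synthetic database described in [sim_config()] and returns
#' the three longitudinal tables plus the generation ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_ehr"` with elements `patients`,
#'   `prescriptions`, `diagnoses` (data frames in the package's standard
#'   schemas) and `truth` (true odds ratios and realized counts).
#' @export
sim_ehr <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  end_study <- as_day(config$first_rx_window[2])

  ## --- patients -----------------------------------------------------------
  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prob_male, "M", "F")
  b0 <- as_day(as.Date(sprintf("%d-01-01", config$birth_year_range[1])))
  b1 <- as_day(as.Date(sprintf("%d-12-31", config$birth_year_range[2])))
  birth <- b0 + floor(stats::runif(n) * (b1 - b0 + 1))
  f0 <- as_day(config$first_rx_window[1])
  first_rx <- f0 + floor(stats::runif(n) * (end_study - f0 + 1))

  ## --- antipsychotic episodes --------------------------------------------
  n_ep <- 1L + stats::rnbinom(n, size = config$episodes_dispersion,
                              mu = config$episodes_mean)
  N <- sum(n_ep)
  row_pat <- rep.int(seq_len(n), n_ep)
  len <- pmax(1, round(stats::rlnorm(N, config$episode_log_mean,
                                     config$episode_log_sd)))
  gap <- round(stats::rexp(N, 1 / config$gap_mean_days))
  overlap <- stats::runif(N) < config$overlap_prob
  ov_days <- floor(stats::runif(N) * 15)
  first_row <- c(TRUE, row_pat[-1] != row_pat[-N])
  len_prev <- c(0, len[-N])
  # increment from previous start to this start; overlaps bounded so starts
  # stay non-decreasing within a patient
  inc <- ifelse(overlap,
                pmax(len_prev - 1 - pmin(ov_days, pmax(len_prev - 1, 0)), 0),
                len_prev - 1 + 1 + gap)
  inc[first_row] <- 0
  cs <- cumsum(inc)
  base <- cs[first_row][row_pat]
  start <- first_rx[row_pat] + (cs - base)
  end <- start + len - 1

  is_flu_user <- stats::runif(n) < config$prob_flupentixol_user
  others <- other_antipsychotics()
  drug <- sample(others, N, replace = TRUE)
  flu_ep <- is_flu_user[row_pat] & stats::runif(N) < config$flup_episode_prob
  drug[flu_ep] <- "flupentixol"

  # the database extract ends at the study cutoff: episodes that would start
  # after it are never observed (each patient keeps at least the first one)
  keep <- start <= end_study
  row_pat <- row_pat[keep]; start <- start[keep]; end <- end[keep]
  len <- len[keep]; drug <- drug[keep]
  N <- length(start)

  ## --- true cumulative exposure (merged union intervals per patient) ------
  merged <- merge_intervals_by(row_pat, start, end)

  ## --- covariates ---------------------------------------------------------
  prev <- config$covariate_prevalences[covariate_names()]
  Z <- matrix(stats::runif(n * 21L) < rep(prev, each = n), nrow = n)
  colnames(Z) <- covariate_names()
  gamma <- config$covariate_log_ors[covariate_names()]
  gamma[is.na(gamma)] <- 0
  risk_z <- drop(Z %*% gamma)

  ## --- outcome on the 30-day grid ----------------------------------------
  K <- pmax(0L, (end_study - first_rx) %/% 30L)
  steps_pat <- rep.int(seq_len(n), K)
  k <- sequence(K)
  t_step <- first_rx[steps_pat] + 30L * k
  cum <- coverage_before(merged, steps_pat, t_step)
  cat <- exposure_category(cum, c(365L, 1825L))
  lp <- config$baseline_hazard_logit +
    config$true_log_or_cat2 * (cat == 2L) +
    config$true_log_or_cat3 * (cat == 3L) +
    risk_z[steps_pat]
  u_cancer <- stats::runif(length(k))
  u_death <- stats::runif(length(k))
  hit_ca <- u_cancer < stats::plogis(lp)
  hit_de <- u_death < config$death_hazard_per_step
  k_ca <- first_hit_step(steps_pat, k, hit_ca, n)
  k_de <- first_hit_step(steps_pat, k, hit_de, n)
  # cancer checked before death within a step, so ties go to cancer
  is_case <- !is.na(k_ca) & (is.na(k_de) | k_ca <= k_de)
  cancer_day <- ifelse(is_case, first_rx + 30L * k_ca, NA_integer_)
  death_day <- ifelse(!is.na(k_de), first_rx + 30L * k_de, NA_integer_)

  subtype <- sample(names(config$subtype_weights), sum(is_case),
                    replace = TRUE, prob = config$subtype_weights)

  ## --- co-medication prescriptions ---------------------------------------
  comed_specs <- list(nsaids = c("ibuprofen", "nsaid"),
                      statins = c("simvastatin", "statin"),
                      aspirin = c("aspirin", "aspirin"),
                      metformin = c("metformin", "metformin"))
  comed <- do.call(rbind, lapply(names(comed_specs), function(nm) {
    who <- which(Z[, nm])
    if (!length(who)) return(NULL)
    s <- f0 + floor(stats::runif(length(who)) * (end_study - f0 + 1))
    data.frame(patient_id = pid[who],
               drug_code = comed_specs[[nm]][1],
               drug_class = comed_specs[[nm]][2],
               start_date = day_to_date(s),
               end_date = day_to_date(s + 29L),
               dosage = 1, frequency_per_day = 1, quantity = 30,
               stringsAsFactors = FALSE)
  }))

  ## --- comorbidity diagnoses ----------------------------------------------
  cls <- default_codelists()
  dx_flags <- covariate_names()[5:21]
  dx <- do.call(rbind, lapply(dx_flags, function(nm) {
    who <- which(Z[, nm])
    if (!length(who)) return(NULL)
    d <- f0 + floor(stats::runif(length(who)) * (end_study - f0 + 1))
    code <- cls[[nm]]$codes[1]
    # emit a concrete child code of the prefix where the prefix is 3-digit
    if (!grepl("\\.", code)) code <- paste0(code, ".0")
    data.frame(patient_id = pid[who], icd9_code = code,
               diagnosis_date = day_to_date(d), stringsAsFactors = FALSE)
  }))

  lung_dx <- data.frame(patient_id = pid[is_case],
                        icd9_code = subtype,
                        diagnosis_date = day_to_date(cancer_day[is_case]),
                        stringsAsFactors = FALSE)
  diagnoses <- rbind(dx, lung_dx)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$diagnosis_date,
                               diagnoses$icd9_code), , drop = FALSE]
  rownames(diagnoses) <- NULL

  ## --- observed antipsychotic prescription table --------------------------
  # consistent dispensing fields: quantity = dosage * frequency * duration,
  # so level-2 imputation can reconstruct the duration arithmetically
  dosage <- sample(c(1, 2), N, replace = TRUE)
  freq <- sample(c(1, 2, 3), N, replace = TRUE)
  quantity <- dosage * freq * len
  miss_end <- stats::runif(N) < config$missing_end_date_rate
  keep_fields <- stats::runif(N) < config$missing_keep_fields_prob
  end_obs <- day_to_date(end)
  end_obs[miss_end] <- NA
  dosage[miss_end & !keep_fields] <- NA
  freq[miss_end & !keep_fields] <- NA
  quantity[miss_end & !keep_fields] <- NA
  rx_ap <- data.frame(patient_id = pid[row_pat],
                      drug_code = drug,
                      drug_class = "antipsychotic",
                      start_date = day_to_date(start),
                      end_date = end_obs,
                      dosage = dosage, frequency_per_day = freq,
                      quantity = quantity, stringsAsFactors = FALSE)
  prescriptions <- rbind(rx_ap, comed)
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$start_date,
                                       prescriptions$drug_code), , drop = FALSE]
  rownames(prescriptions) <- NULL

  patients <- data.frame(patient_id = pid, sex = sex,
                         birth_date = day_to_date(birth),
                         death_date = day_to_date(death_day),
                         stringsAsFactors = FALSE)

  truth <- list(
    true_or_cat2 = exp(config$true_log_or_cat2),
    true_or_cat3 = exp(config$true_log_or_cat3),
    covariate_ors = as.list(exp(gamma)),
    n_patients = n,
    n_cases = sum(is_case),
    n_prescriptions = nrow(prescriptions)
  )
  structure(list(patients = patients, prescriptions = prescriptions,
                 diagnoses = diagnoses, truth = truth, config = config),
            class = "sim_ehr")
}

# merge per-patient episode intervals into disjoint runs, with the
# cumulative number of covered days before each run (for fast lookups)
merge_intervals_by <- function(pat, start, end) {
  o <- order(pat, start, end)
  pat <- pat[o]; start <- start[o]; end <- end[o]
  run_end <- end
  first <- c(TRUE, pat[-1] != pat[-length(pat)])
  # cummax within patient
  grp_reset <- which(first)
  run_end <- unlist(lapply(split(end, cumsum(first)), cummax), use.names = FALSE)
  new_run <- first | (start > c(-1L, run_end[-length(run_end)]) + 1L)
  g <- cumsum(new_run)
  ms <- start[new_run]
  me <- as.integer(tapply(run_end, g, max))
  mp <- pat[new_run]
  covered <- me - ms + 1L
  firstm <- c(TRUE, mp[-1] != mp[-length(mp)])
  cs <- cumsum(c(0L, covered[-length(covered)]))
  cs[firstm] <- 0L
  # cumulative covered days before each merged run, within patient
  csw <- cumsum(covered) - covered
  base <- csw[firstm][match(mp, mp[firstm])]
  cum_before <- csw - base
  list(pat = mp, start = ms, end = me, cum_before = cum_before)
}

# cumulative covered days strictly before day t for (patient, t) queries
coverage_before <- function(merged, q_pat, q_t) {
  M <- 1e6
  ikey <- merged$pat * M + merged$start
  qkey <- q_pat * M + (q_t - 1)
  j <- findInterval(qkey, ikey)
  out <- numeric(length(qkey))
  ok <- j > 0L
  jj <- j[ok]
  same <- merged$pat[jj] == q_pat[ok]
  res <- numeric(sum(ok))
  res[same] <- merged$cum_before[jj[same]] +
    pmax(0, pmin(merged$end[jj[same]], q_t[ok][same] - 1) -
              merged$start[jj[same]] + 1)
  # j pointing into an earlier patient means no interval starts before t
  out[ok] <- res
  as.integer(out)
}

# first step index k at which `hit` is TRUE, per patient; NA if never
first_hit_step <- function(pat, k, hit, n) {
  out <- rep.int(NA_integer_, n)
  w <- which(hit)
  if (!length(w)) return(out)
  # rows are ordered by (patient, k); the first hit row per patient wins
  firsts <- w[!duplicated(pat[w])]
  out[pat[firsts]] <- k[firsts]
  out
}

#' Write synthetic tables to delimited text files
#'
#' Writes `patients.csv`, `prescriptions.csv`, `diagnoses.csv` and
#' `truth.json` (plain-text JSON written without external dependencies) into
#' `directory`.
#'
#' @param ehr A [sim_ehr()] result.
#' @param directory Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_ehr_tables <- function(ehr, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(directory, "patients.csv"),
             prescriptions = file.path(directory, "prescriptions.csv"),
             diagnoses = file.path(directory, "diagnoses.csv"),
             truth = file.path(directory, "truth.json"))
  utils::write.csv(ehr$patients, paths["patients"], row.names = FALSE, na = "")
  utils::write.csv(ehr$prescriptions, paths["prescriptions"],
                   row.names = FALSE, na = "")
  utils::write.csv(ehr$diagnoses, paths["diagnoses"], row.names = FALSE, na = "")
  tr <- ehr$truth
  scal <- function(x) {
    if (is.character(x)) paste0('"', x, '"') else format(x, digits = 15)
  }
  fields <- vapply(names(tr), function(nm) {
    v <- tr[[nm]]
    if (is.list(v)) {
      inner <- paste0('"', names(v), '": ', vapply(v, scal, ""), collapse = ", ")
      paste0('"', nm, '": {', inner, "}")
    } else paste0('"', nm, '": ', scal(v))
  }, "")
  writeLines(paste0("{", paste(fields, collapse = ", "), "}"), paths["truth"])
  invisible(paths)
}

#' Read EHR tables written by [write_ehr_tables()] (or any data in the same
#' schema)
#'
#' @param directory Directory holding `patients.csv`, `prescriptions.csv`,
#'   `diagnoses.csv`.
#' @return List with `patients`, `prescriptions`, `diagnoses` data frames
#'   with parsed `Date` columns.
#' @export
read_ehr_tables <- function(directory) {
  pat <- utils::read.csv(file.path(directory, "patients.csv"),
                         colClasses = "character")
  pat$birth_date <- as.Date(pat$birth_date)
  pat$death_date <- parse_date_opt(pat$death_date)
  rx <- utils::read.csv(file.path(directory, "prescriptions.csv"),
                        colClasses = "character")
  rx$start_date <- parse_date_opt(rx$start_date)
  rx$end_date <- parse_date_opt(rx$end_date)
  for (cc in c("dosage", "frequency_per_day", "quantity"))
    rx[[cc]] <- suppressWarnings(as.numeric(rx[[cc]]))
  dx <- utils::read.csv(file.path(directory, "diagnoses.csv"),
                        colClasses = "character")
  dx$diagnosis_date <- as.Date(dx$diagnosis_date)
  list(patients = pat, prescriptions = rx, diagnoses = dx)
}
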