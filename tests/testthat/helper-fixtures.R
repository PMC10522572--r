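# Shared fixtures, all built in code.

# hand-built three-table micro-cohort exercising every screening rule
tiny_tables <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F", "G"),
    sex = c("M", "M", "F", NA, "F", "M", "F"),
    birth_date = as.Date(c("1950-03-10", "1950-03-10", "1940-06-02",
                           "1960-01-01", "1945-05-05", "1950-03-10",
                           "1940-06-02")),
    death_date = as.Date(c(NA, "2003-01-01", NA, NA, NA, NA, NA)),
    stringsAsFactors = FALSE)
  prescriptions <- data.frame(
    patient_id = c("A", "A", "B", "C", "D", "E", "F", "G"),
    drug_code = c("quetiapine", "flupentixol", "haloperidol", "quetiapine",
                  "quetiapine", "quetiapine", "quetiapine", "quetiapine"),
    drug_class = "antipsychotic",
    start_date = as.Date(c("2005-03-01", "2004-01-10", "2004-05-05",
                           "2004-02-01", "2004-02-01", "2001-06-01",
                           "2004-02-01", "2004-02-01")),
    end_date = as.Date(c("2005-03-28", "2004-02-10", "2004-06-05",
                         "2004-03-01", "2004-03-01", "2001-06-30",
                         "2004-03-01", "2004-03-01")),
    dosage = 1, frequency_per_day = 1, quantity = 30,
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = c("E", "F", "G", "G"),
    icd9_code = c("162.9", "162.3", "162.9", "162.3"),
    diagnosis_date = as.Date(c("2002-06-01", "2004-02-01", "2010-06-01",
                               "2010-06-01")),
    stringsAsFactors = FALSE)
  # A: clean; B: death before first rx (rule 2); C: clean; D: missing sex
  # (rule 1); E: lung cancer before outcome window (rule 4); F: lung cancer
  # on the day of the first rx (rule 3); G: incident case 2010-06-01 with a
  # same-day subtype tie (162.3 should win).
  list(patients = patients, prescriptions = prescriptions,
       diagnoses = diagnoses)
}

# random matched-set design for likelihood tests
random_design <- function(n_sets, m, p, seed) {
  set.seed(seed)
  n <- n_sets * (m + 1L)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  set <- rep(seq_len(n_sets), each = m + 1L)
  case <- rep(c(TRUE, rep(FALSE, m)), n_sets)
  list(X = X, case = case, set = set)
}

# brute-force conditional log-likelihood, written independently of the
# package's sweep/rowsum implementation
brute_loglik <- function(X, case, set, beta) {
  sum(vapply(unique(set), function(s) {
    rows <- which(set == s)
    eta <- as.numeric(X[rows, , drop = FALSE] %*% beta)
    eta[case[rows]] - log(sum(exp(eta)))
  }, 0))
}

# brute-force union day count by explicit day-set enumeration
brute_union_days <- function(start, end, index_day = NULL) {
  days <- unlist(mapply(function(s, e) seq.int(s, e), start, end,
                        SIMPLIFY = FALSE))
  if (!is.null(index_day)) days <- days[days < index_day]
  length(unique(days))
}

# small synthetic EHR shared across tests (generated once per test run)
small_ehr <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_ehr(sim_config(n_patients = 1500, seed = 2024))
    cache
  }
})

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ehr <- small_ehr()
      cache <<- ncc_data(ehr[c("patients", "prescriptions", "diagnoses")],
                         study_config(), seed = 5)
    }
    cache
  }
})
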