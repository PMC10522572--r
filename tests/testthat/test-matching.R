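# Incidence-density sampling with sex/age matching and a reuse cap.

match_pool <- function() {
  # 30-patient hand-built pool: variations of sex, age, timing, death, cancer
  n <- 30
  data.frame(
    patient_id = sprintf("C%02d", 1:n),
    sex = rep(c("M", "F"), 15),
    birth_date = as.Date("1950-06-15") + rep(c(0, 0, 0, 365, -365), 6),
    death_date = as.Date(ifelse(1:n %% 7 == 0, "2009-01-01", NA)),
    first_ap_date = as.Date(ifelse(1:n %% 5 == 0, "2010-06-01", "2004-03-01")),
    first_lc_date = as.Date(ifelse(1:n %% 11 == 0, "2015-01-01", NA)),
    stringsAsFactors = FALSE)
}

the_case <- function() data.frame(
  patient_id = "X", index_date = as.Date("2010-06-01"),
  age_at_index = age_completed(as.Date("1950-06-15"), as.Date("2010-06-01")),
  sex = "M", subtype_code = "162.9", stringsAsFactors = FALSE)

test_that("candidate set equals exhaustive predicate evaluation", {
  pool <- match_pool()
  cs <- the_case()
  got <- eligible_controls(cs, pool)
  want <- pool$patient_id[vapply(seq_len(nrow(pool)), function(i) {
    p <- pool[i, ]
    p$sex == cs$sex &&
      age_completed(p$birth_date, cs$index_date) == cs$age_at_index &&
      !is.na(p$first_ap_date) && p$first_ap_date < cs$index_date &&
      (is.na(p$first_lc_date) || p$first_lc_date > cs$index_date) &&
      (is.na(p$death_date) || p$death_date > cs$index_date) &&
      p$patient_id != cs$patient_id
  }, TRUE)]
  expect_setequal(got, want)
  expect_gt(length(got), 0)
})

test_that("a future case is an eligible control before its own diagnosis", {
  pool <- match_pool()
  cs <- the_case()
  # C11 has lung cancer 2015-01-01, after the 2010 index date
  expect_true(all(is.na(pool$first_lc_date) |
                    pool$first_lc_date == as.Date("2015-01-01")))
  got <- eligible_controls(cs, pool)
  expect_true("C11" %in% got)
  # but not for an index date on/after its diagnosis
  cs2 <- cs
  cs2$index_date <- as.Date("2015-01-01")
  cs2$age_at_index <- age_completed(as.Date("1950-06-15"), cs2$index_date)
  expect_false("C11" %in% eligible_controls(cs2, pool))
})

test_that("first antipsychotic on the index date itself is ineligible", {
  pool <- match_pool()
  cs <- the_case()
  # patients with first_ap 2010-06-01 == index date must be excluded
  on_day <- pool$patient_id[pool$first_ap_date == cs$index_date]
  expect_gt(length(on_day), 0)
  expect_false(any(on_day %in% eligible_controls(cs, pool)))
})

test_that("matching honours ratio, cap exhaustion and determinism", {
  pool <- match_pool()
  cs <- the_case()
  cfg <- study_config()

  # single eligible candidate -> set of exactly one control
  pool1 <- pool[pool$patient_id == "C01", ]
  m1 <- match_controls(cs, pool1, cfg, seed = 1)
  expect_equal(sum(m1$sets$role == "control"), 1L)

  # cap of 1: two same-demography cases, one candidate; second set dropped
  cases2 <- rbind(cs, within(cs, {
    patient_id <- "Y"; index_date <- as.Date("2010-06-02")
  }))
  cases2$age_at_index <- age_completed(as.Date("1950-06-15"), cases2$index_date)
  cfg1 <- study_config(max_control_reuse = 1)
  m2 <- match_controls(cases2, pool1, cfg1, seed = 1)
  expect_equal(sum(m2$sets$role == "control"), 1L)
  expect_true(any(m2$log$dropped))

  # determinism: identical inputs and seed give identical output
  cases3 <- data.frame(patient_id = c("X1", "X2", "X3"),
                       index_date = as.Date("2010-06-01") + c(0, 10, 20),
                       sex = "M", subtype_code = "162.9",
                       stringsAsFactors = FALSE)
  cases3$age_at_index <- age_completed(as.Date("1950-06-15"), cases3$index_date)
  a <- match_controls(cases3, pool, cfg, seed = 42)
  b <- match_controls(cases3, pool, cfg, seed = 42)
  expect_identical(a$sets, b$sets)
  c2 <- match_controls(cases3, pool, cfg, seed = 43)
  expect_false(identical(a$sets, c2$sets))  # the seed drives the draw
})

test_that("matched sets satisfy every design invariant on a synthetic run", {
  b <- small_bundle()
  m <- b$members
  cfg <- b$config
  pts <- b$tables$patients
  first_ap <- first_antipsychotic_date(b$tables$prescriptions, cfg)
  lc <- b$tables$diagnoses[startsWith(b$tables$diagnoses$icd9_code, "162"), ]
  first_lc <- tapply(as_day(lc$diagnosis_date), lc$patient_id, min)

  per_set <- split(m, m$set_id)
  expect_true(all(vapply(per_set, function(s) sum(s$role == "case") == 1L, TRUE)))
  expect_true(all(vapply(per_set, function(s)
    sum(s$role == "control") >= 1L &&
      sum(s$role == "control") <= cfg$matching_ratio, TRUE)))
  # sex and completed age homogeneous within sets
  birth <- pts$birth_date[match(m$patient_id, pts$patient_id)]
  sex <- pts$sex[match(m$patient_id, pts$patient_id)]
  age <- age_completed(birth, m$index_date)
  expect_true(all(tapply(sex, m$set_id, function(x) length(unique(x)) == 1L)))
  expect_true(all(tapply(age, m$set_id, function(x) length(unique(x)) == 1L)))
  # every control: exposure before index, cancer-free at index, alive
  ctrl <- m[m$role == "control", ]
  expect_true(all(first_ap[as.character(ctrl$patient_id)] < ctrl$index_date))
  flc <- first_lc[as.character(ctrl$patient_id)]
  expect_true(all(is.na(flc) | flc > as_day(ctrl$index_date)))
  death <- pts$death_date[match(ctrl$patient_id, pts$patient_id)]
  expect_true(all(is.na(death) | death > ctrl$index_date))
  # a case is never a control in its own set
  expect_true(all(vapply(per_set, function(s)
    !s$patient_id[s$role == "case"] %in% s$patient_id[s$role == "control"],
    TRUE)))
  # reuse cap respected globally
  uses <- table(ctrl$patient_id)
  expect_true(all(uses <= cfg$max_control_reuse))
})

test_that("unlimited reuse selects at least as many controls as the cap", {
  ehr <- small_ehr()
  tabs <- ehr[c("patients", "prescriptions", "diagnoses")]
  scr <- screen_cohort(tabs$patients, tabs$prescriptions, tabs$diagnoses,
                       study_config())
  cases <- identify_cases(scr$eligible, tabs$diagnoses, study_config())
  capped <- match_controls(cases, scr$eligible, study_config(), seed = 9)
  unlim <- match_controls(cases, scr$eligible,
                          study_config(max_control_reuse = Inf), seed = 9)
  expect_gte(sum(unlim$sets$role == "control"),
             sum(capped$sets$role == "control"))
})

test_that("duplicate case ids are a hard error", {
  cs <- the_case()
  expect_error(match_controls(rbind(cs, cs), match_pool(), study_config(), 1),
               "duplicate")
})
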