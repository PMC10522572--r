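# Duration resolution, interval-union counting and exposure summaries.

day <- function(x) as_day(as.Date(x))

test_that("complete records resolve to their recorded interval", {
  rx <- data.frame(patient_id = "A", drug_code = "d",
                   start_date = as.Date("2010-01-01"),
                   end_date = as.Date("2010-01-28"),
                   dosage = NA, frequency_per_day = NA, quantity = NA)
  res <- resolve_durations(rx, duration_imputer(rx))
  expect_equal(res$start, day("2010-01-01"))
  expect_equal(res$end, day("2010-01-28"))
  expect_equal(res$end - res$start + 1L, 28L)
  expect_equal(res$resolution_level, 1L)
})

test_that("level-2 imputation uses ceil(quantity / (dosage * frequency))", {
  rx <- data.frame(patient_id = "A", drug_code = "d",
                   start_date = as.Date(c("2010-01-01", NA)),
                   end_date = as.Date(c(NA, "2010-03-28")),
                   dosage = 1, frequency_per_day = 2, quantity = 56)
  res <- resolve_durations(rx, duration_imputer(rx))
  expect_equal(res$resolution_level, c(2L, 2L))
  # anchored at start: end = start + 28 - 1
  expect_equal(res$end[1], day("2010-01-28"))
  # anchored at end: start = end - 28 + 1
  expect_equal(res$start[2], day("2010-03-01"))
  # odd quantity rounds the duration up
  rx$quantity <- 57
  res2 <- resolve_durations(rx, duration_imputer(rx))
  expect_equal(res2$end[1] - res2$start[1] + 1L, 29L)
})

test_that("level-3 imputation uses the per-drug median with global fallback", {
  complete <- data.frame(patient_id = "A", drug_code = "d",
                         start_date = as.Date("2011-01-01") + c(0, 100, 200),
                         end_date = as.Date("2011-01-01") + c(6, 113, 227),
                         dosage = NA, frequency_per_day = NA, quantity = NA)
  imp <- duration_imputer(complete)  # durations 7, 14, 28 -> median 14
  expect_equal(unname(imp$per_drug["d"]), 14)
  inc <- data.frame(patient_id = "A", drug_code = "d",
                    start_date = as.Date("2012-01-01"), end_date = as.Date(NA),
                    dosage = NA, frequency_per_day = NA, quantity = NA)
  res <- resolve_durations(inc, imp)
  expect_equal(res$resolution_level, 3L)
  expect_equal(res$end - res$start + 1L, 14L)
  # unseen drug falls back to the global median
  inc$drug_code <- "other"
  expect_equal(with(resolve_durations(inc, imp), end - start + 1L), 14L)
})

test_that("zero dosage*frequency falls through to level 3", {
  complete <- data.frame(patient_id = "A", drug_code = "d",
                         start_date = as.Date("2011-01-01"),
                         end_date = as.Date("2011-01-10"),
                         dosage = NA, frequency_per_day = NA, quantity = NA)
  imp <- duration_imputer(complete)
  rx <- data.frame(patient_id = "A", drug_code = "d",
                   start_date = as.Date("2012-01-01"), end_date = as.Date(NA),
                   dosage = 0, frequency_per_day = 2, quantity = 56)
  res <- resolve_durations(rx, imp)
  expect_equal(res$resolution_level, 3L)
})

test_that("records with neither date are dropped with a warning", {
  rx <- data.frame(patient_id = c("A", "A"), drug_code = "d",
                   start_date = as.Date(c("2010-01-01", NA)),
                   end_date = as.Date(c("2010-01-05", NA)),
                   dosage = 1, frequency_per_day = 1, quantity = 5)
  expect_warning(res <- resolve_durations(rx, duration_imputer(rx)),
                 "neither date")
  expect_equal(nrow(res), 1L)
})

test_that("union counting merges overlaps and truncates at the index date", {
  s <- day(c("2020-01-01", "2020-01-05"))
  e <- day(c("2020-01-10", "2020-01-20"))
  expect_equal(union_days(s, e, day("2020-03-01")), 20L)
  expect_equal(union_days(day("2020-01-01"), day("2020-01-10"),
                          day("2020-01-06")), 5L)
  expect_equal(union_days(integer(0), integer(0), 100L), 0L)
  # interval entirely on/after the index date contributes nothing
  expect_equal(union_days(day("2020-02-01"), day("2020-02-10"),
                          day("2020-02-01")), 0L)
})

test_that("union is invariant to input order and interval splitting", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(0:60, n, replace = TRUE)
    idx <- 400L
    base <- union_days(s, e, idx)
    o <- sample(n)
    expect_identical(union_days(s[o], e[o], idx), base)
    # split the longest interval into two adjacent halves
    j <- which.max(e - s)
    if (e[j] > s[j]) {
      mid <- s[j] + (e[j] - s[j]) %/% 2
      s2 <- c(s[-j], s[j], mid + 1L)
      e2 <- c(e[-j], mid, e[j])
      expect_identical(union_days(s2, e2, idx), base)
    }
  }
})

test_that("sweep union equals explicit day-set enumeration on random input", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(1:60, 1)
    s <- sample(0:2000, n, replace = TRUE)
    e <- s + sample(0:90, n, replace = TRUE)
    idx <- sample(0:2200, 1)
    expect_identical(union_days(s, e, idx), brute_union_days(s, e, idx))
    expect_identical(union_days(s, e), brute_union_days(s, e))
  }
})

test_that("per-drug days honour the union/raw-sum switch", {
  s <- day(c("2020-01-01", "2020-01-05"))
  e <- day(c("2020-01-10", "2020-01-20"))
  expect_equal(drug_days(s, e, day("2020-03-01"), union = TRUE), 20L)
  expect_equal(drug_days(s, e, day("2020-03-01"), union = FALSE), 26L)
  expect_equal(drug_days(integer(0), integer(0), 1L), 0L)
})

test_that("exposure summaries categorize at the documented boundaries", {
  mk_rx <- function(days) data.frame(
    patient_id = "A", drug_code = "flupentixol", drug_class = "antipsychotic",
    start_date = as.Date("2010-01-01"),
    end_date = as.Date("2010-01-01") + days - 1,
    dosage = NA, frequency_per_day = NA, quantity = NA)
  cfg <- study_config()
  member <- data.frame(patient_id = "A", index_date = as.Date("2020-01-01"))
  for (case in list(c(365L, 1L), c(366L, 2L), c(1825L, 2L), c(1826L, 3L))) {
    sm <- summarize_exposure(member, mk_rx(case[1]), cfg)
    expect_equal(sm$days_any, case[1])
    expect_equal(sm$cat_any, case[2])
    expect_equal(sm$cat_flupentixol, case[2])
  }
})

test_that("exposure summary invariants hold on synthetic members", {
  b <- small_bundle()
  m <- b$members
  expect_true(all(m$days_any >= pmax(m$days_flupentixol, m$days_other)))
  expect_true(all(m$days_any <= m$days_flupentixol + m$days_other))
  expect_true(all(m$days_any >= 1L))
  # exposure never exceeds time from first antipsychotic to the index date
  first_ap <- first_antipsychotic_date(b$tables$prescriptions, b$config)
  gap <- as_day(m$index_date) - as_day(first_ap[as.character(m$patient_id)])
  expect_true(all(m$days_any <= gap))
  cp <- b$config$cut_points
  expect_identical(m$cat_any,
                   findInterval(m$days_any, c(cp[1] + 1L, cp[2] + 1L)) + 1L)
})

test_that("a member with zero pre-index exposure is a hard error", {
  rx <- data.frame(patient_id = "A", drug_code = "d",
                   drug_class = "antipsychotic",
                   start_date = as.Date("2020-06-01"),
                   end_date = as.Date("2020-06-30"),
                   dosage = NA, frequency_per_day = NA, quantity = NA)
  member <- data.frame(patient_id = "A", index_date = as.Date("2020-01-01"))
  expect_error(summarize_exposure(member, rx, study_config()), "zero days")
})
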