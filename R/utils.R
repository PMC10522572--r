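#' @keywords internal
"_PACKAGE"

# Internal date helpers. Dates are stored as Date; arithmetic is done on
# integer day numbers (days since 1970-01-01) so interval work is exact.

as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(unclass(x)))
  as.integer(unclass(as.Date(x)))
}

day_to_date <- function(x) as.Date(x, origin = "1970-01-01")

#' Completed age in years at a reference date
#'
#' Age by the "birthday" convention: the number of whole years elapsed, i.e.
#' the age decrements by one if the birthday has not yet occurred in the
#' reference year. Matching and case eligibility both use this convention.
#'
#' @param birth_date,at_date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @examples
#' age_completed(as.Date("1940-06-02"), as.Date("2010-06-01")) # 69
#' age_completed(as.Date("1940-06-02"), as.Date("2010-06-02")) # 70
#' @export
age_completed <- function(birth_date, at_date) {
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at_date)
  yrs <- a$year - b$year
  not_yet <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - not_yet)
}

# parse "" as NA for optional date columns read from text
parse_date_opt <- function(x) {
  x[!nzchar(x)] <- NA_character_
  as.Date(x)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
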