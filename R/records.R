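#' Construct a table of individual mortality records
#'
#' One row per death. Age at death is recorded in completed integer years as
#' it appears on a death certificate; no fractional-age interpolation is
#' applied anywhere downstream.
#'
#' @param age Integer vector of ages at death in years (>= 0).
#' @param cause Character vector of free-text cause labels (recycled).
#' @param year Optional calendar year of death (recycled).
#' @param sex Optional sex label (recycled).
#' @return A tibble with class `mortality_records` and columns `age`, `cause`,
#'   `year`, `sex`.
#' @examples
#' mortality_records(c(42, 67, 15), cause = "stroke")
#' @export
mortality_records <- function(age, cause = "unspecified", year = NA_integer_,
                              sex = NA_character_) {
  if (length(age) > 0 && (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)))
    stop_domain("`age` must be non-negative finite numbers")
  if (length(age) > 0 && any(age != round(age)))
    stop_domain("`age` must be whole years as recorded on death certificates")
  out <- tibble::tibble(age = as.integer(age),
                        cause = rep_len(as.character(cause), length(age)),
                        year = rep_len(as.integer(year), length(age)),
                        sex = rep_len(as.character(sex), length(age)))
  class(out) <- c("mortality_records", class(out))
  out
}

#' Read mortality records from delimited text
#'
#' Expects comma-separated UTF-8 text with a header row naming at least an
#' `age` column; `cause`, `year` and `sex` are used when present and any other
#' columns are ignored. Rows whose age is missing, non-numeric or negative
#' are malformed: they are reported with their line numbers and either
#' skipped (default) or made fatal with `strict = TRUE`.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE`, any malformed row aborts the read; if `FALSE`
#'   malformed rows are dropped with a warning listing their line numbers.
#' @return A [mortality_records()] tibble.
#' @export
read_mortality_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_io("records file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  if (!"age" %in% names(raw))
    stop_io("records file %s has no `age` column", path)
  age_num <- suppressWarnings(as.numeric(raw$age))
  bad <- is.na(age_num) | age_num < 0 | (is.finite(age_num) & age_num != round(age_num))
  if (any(bad)) {
    # +1 for the header row: report line numbers as they appear in the file
    lines <- which(bad) + 1L
    msg <- sprintf("%d malformed record row(s) at line(s) %s of %s",
                   sum(bad), paste(lines, collapse = ", "), path)
    if (strict) stop_io("%s", msg)
    warning(msg, call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    age_num <- age_num[!bad]
  }
  grab <- function(col, default) if (col %in% names(raw)) raw[[col]] else default
  mortality_records(age = age_num,
                    cause = grab("cause", "unspecified"),
                    year = suppressWarnings(as.integer(grab("year", NA))),
                    sex = grab("sex", NA_character_))
}

#' Write mortality records as delimited text
#'
#' Emits the same CSV format [read_mortality_records()] reads (header
#' `age,cause,year,sex`), so generated synthetic files round-trip exactly.
#'
#' @param records A [mortality_records()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality_records <- function(records, path) {
  stopifnot(inherits(records, "mortality_records"))
  utils::write.csv(as.data.frame(records)[, c("age", "cause", "year", "sex")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Keep only working-age deaths
#'
#' Retains records with `working_age_min <= age <= working_age_max`, both
#' bounds inclusive, in their original order. In the Fiji costing this is the
#' 15--55 window defining "young" stroke mortality.
#'
#' @param records A [mortality_records()] tibble.
#' @param params An [economic_params()] object supplying the window.
#' @return The filtered records, same class and column layout.
#' @export
filter_working_age <- function(records, params) {
  stopifnot(inherits(records, "mortality_records"),
            inherits(params, "economic_params"))
  keep <- records$age >= params$working_age_min &
    records$age <= params$working_age_max
  records[keep, , drop = FALSE]
}

#' Years to retirement
#'
#' The remaining working lifespan lost: retirement age minus age at death.
#' Records above the retirement age have no remaining working life and are a
#' domain error here — they should have been removed by the working-age
#' filter.
#'
#' @param age Integer vector of ages at death (or a [mortality_records()]
#'   tibble, whose `age` column is used).
#' @param params An [economic_params()] object.
#' @return Integer vector of years to retirement (>= 0).
#' @examples
#' years_to_retirement(c(15, 50, 55), economic_params())
#' @export
years_to_retirement <- function(age, params) {
  stopifnot(inherits(params, "economic_params"))
  if (inherits(age, "mortality_records")) age <- age$age
  t <- params$retirement_age - as.numeric(age)
  if (any(t < 0))
    stop_domain("record(s) above retirement age %d reached years_to_retirement (max age %g)",
                params$retirement_age, max(age))
  t
}

#' Bin working-age deaths into years-to-retirement cohorts
#'
#' Groups filtered records into cohorts of width `bin_width` years to
#' retirement, rounding each individual's remaining working lifespan UP to
#' the nearest positive multiple of the width: with the default width 5,
#' t in (0,5\] maps to the 5-year cohort, (5,10\] to 10, and so on. Deaths
#' exactly at retirement age (t = 0) carry zero remaining work-life and are
#' excluded. The ceiling rule grants each death an annuity horizon at least
#' as long as its true remaining lifespan, never more than `bin_width - 1`
#' years longer.
#'
#' @param records Working-age-filtered [mortality_records()].
#' @param params An [economic_params()] object.
#' @param bin_width Cohort width in years (> 0); default 5.
#' @return Named integer vector mapping cohort `t` to death count, ordered by
#'   decreasing `t`. Counts sum to the number of records with `t > 0`.
#' @examples
#' rec <- mortality_records(c(15, 16, 54, 55))
#' bin_to_cohorts(rec, economic_params())
#' @export
bin_to_cohorts <- function(records, params, bin_width = 5) {
  stopifnot(inherits(records, "mortality_records"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop_domain("`bin_width` must be a single positive number")
  t <- years_to_retirement(records, params)
  t <- t[t > 0]
  if (length(t) == 0L) return(stats::setNames(integer(0), character(0)))
  bins <- ceiling(t / bin_width) * bin_width
  tab <- table(bins)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(as.numeric(names(out)), decreasing = TRUE)]
}
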