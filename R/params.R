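#' Economic parameters for human-capital valuation
#'
#' Bundles the economic inputs of the human-capital method: the annual income
#' each death is assumed to forego (proxied by per-capita national income when
#' individual incomes are unknown), the discount rate used to express future
#' income in present-value terms, the statutory retirement age, the inclusive
#' working-age window defining which deaths count as premature losses of
#' productive capacity, and the exchange rate to a secondary reporting
#' currency.
#'
#' Defaults reproduce the Fiji young-stroke costing conditions: per-capita
#' income F$5,131.50, an 8% discount rate, retirement at 55, working ages
#' 15--55 inclusive, and an F$-to-US$ rate of 0.6.
#'
#' @param annual_income Annual income foregone per death, in primary currency
#'   units per year. Must be positive.
#' @param discount_rate Annual discount rate as a fraction (0.08 = 8%). Must be
#'   non-negative; zero is accepted and valued as the undiscounted limit.
#' @param retirement_age Statutory retirement age in whole years.
#' @param working_age_min,working_age_max Inclusive bounds of the working-age
#'   window in years. `working_age_max` defaults to `retirement_age`.
#' @param exchange_rate Secondary-currency units per primary-currency unit.
#'
#' @return An object of class `economic_params` (a named list).
#' @examples
#' economic_params()
#' economic_params(discount_rate = 0.03, retirement_age = 60)
#' @export
economic_params <- function(annual_income = 5131.5,
                            discount_rate = 0.08,
                            retirement_age = 55L,
                            working_age_min = 15L,
                            working_age_max = retirement_age,
                            exchange_rate = 0.6) {
  check_scalar_number(annual_income, "annual_income")
  check_scalar_number(discount_rate, "discount_rate")
  check_scalar_number(retirement_age, "retirement_age")
  check_scalar_number(working_age_min, "working_age_min")
  check_scalar_number(working_age_max, "working_age_max")
  check_scalar_number(exchange_rate, "exchange_rate")
  if (annual_income <= 0)
    stop_domain("`annual_income` must be > 0 (got %g)", annual_income)
  if (discount_rate < 0)
    stop_domain("`discount_rate` must be >= 0 (got %g)", discount_rate)
  if (retirement_age <= 0 || retirement_age != as.integer(retirement_age))
    stop_domain("`retirement_age` must be a positive whole number of years")
  if (exchange_rate <= 0)
    stop_domain("`exchange_rate` must be > 0 (got %g)", exchange_rate)
  if (!(working_age_min < working_age_max && working_age_max <= retirement_age))
    stop_domain(
      "working-age window must satisfy working_age_min < working_age_max <= retirement_age (got %g, %g, %g)",
      working_age_min, working_age_max, retirement_age)
  structure(
    list(annual_income = as.numeric(annual_income),
         discount_rate = as.numeric(discount_rate),
         retirement_age = as.integer(retirement_age),
         working_age_min = as.numeric(working_age_min),
         working_age_max = as.numeric(working_age_max),
         exchange_rate = as.numeric(exchange_rate)),
    class = "economic_params")
}

#' @export
print.economic_params <- function(x, ...) {
  cat("<economic_params>\n")
  cat(sprintf("  annual income foregone : %s / yr\n", fmt_money(x$annual_income, 2)))
  cat(sprintf("  discount rate          : %g%% / yr\n", 100 * x$discount_rate))
  cat(sprintf("  retirement age         : %d yr\n", x$retirement_age))
  cat(sprintf("  working-age window     : [%g, %g] yr (inclusive)\n",
              x$working_age_min, x$working_age_max))
  cat(sprintf("  exchange rate          : %g secondary per primary unit\n",
              x$exchange_rate))
  invisible(x)
}

#' Friction-cost parameters
#'
#' The friction-cost method values lost production only over the "friction
#' period" until a replacement worker restores output, in contrast to the
#' human-capital method which counts the whole remaining working lifespan.
#' The friction period depends on labour availability; the unemployment rate
#' is carried as context metadata (7.6% for Fiji) and does not enter the
#' arithmetic.
#'
#' @param friction_period Years until the deceased worker is replaced (>= 0).
#' @param unemployment_rate Fraction of the labour force unemployed, in
#'   \[0, 1\]. Metadata only.
#'
#' @return An object of class `friction_params`.
#' @examples
#' friction_params(friction_period = 0.25)
#' @export
friction_params <- function(friction_period, unemployment_rate = 0.076) {
  check_scalar_number(friction_period, "friction_period")
  check_scalar_number(unemployment_rate, "unemployment_rate")
  if (friction_period < 0)
    stop_domain("`friction_period` must be >= 0 (got %g)", friction_period)
  if (unemployment_rate < 0 || unemployment_rate > 1)
    stop_domain("`unemployment_rate` must be in [0, 1] (got %g)", unemployment_rate)
  structure(list(friction_period = as.numeric(friction_period),
                 unemployment_rate = as.numeric(unemployment_rate)),
            class = "friction_params")
}

#' @export
print.friction_params <- function(x, ...) {
  cat("<friction_params>\n")
  cat(sprintf("  friction period   : %g yr\n", x$friction_period))
  cat(sprintf("  unemployment rate : %g%% (context only)\n",
              100 * x$unemployment_rate))
  invisible(x)
}
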