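#' Present discounted value of income foregone (human-capital loss)
#'
#' The core annuity of the human-capital method: a worker dying `t` years
#' before retirement foregoes an annual income `S` for each of those years,
#' valued today at discount rate `r` as an ordinary annuity (payments at the
#' end of each year),
#' \deqn{PV = S \frac{1}{r}\left[1 - \frac{1}{(1+r)^t}\right],}
#' which equals the explicit discounted sum \eqn{\sum_{k=1}^{t} S (1+r)^{-k}}
#' for integer `t`. At `r = 0` the continuity limit `S * t` is returned.
#' Income is assumed constant over the remaining working period; no growth
#' term is applied.
#'
#' @param S Annual income foregone (currency units per year, > 0).
#' @param r Annual discount rate as a fraction (>= 0).
#' @param t Years to retirement (>= 0; real values are accepted, the formula
#'   is well defined for non-integer horizons).
#'
#' @return Present value of the foregone income stream, in the currency of
#'   `S`. Vectorised over `t`.
#' @examples
#' present_value_loss(5131.5, 0.08, 40)
#' present_value_loss(100, 0, 10)   # undiscounted limit: 1000
#' @export
present_value_loss <- function(S, r, t) {
  check_scalar_number(S, "S")
  check_scalar_number(r, "r")
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t)))
    stop_domain("`t` must be finite numeric")
  if (S <= 0) stop_domain("`S` must be > 0 (got %g)", S)
  if (r < 0) stop_domain("`r` must be >= 0 (got %g)", r)
  if (any(t < 0)) stop_domain("`t` must be >= 0 (got %g)", min(t))
  if (r == 0) return(S * t)
  # stable form of S (1/r) [1 - (1+r)^-t]: avoids cancellation for small r
  S * (1 / r) * (-expm1(-t * log1p(r)))
}

#' Friction-cost value of a premature death
#'
#' Comparator to [present_value_loss()]: under the friction-cost view society
#' restores production once the worker is replaced, so output is lost only
#' over the friction period. Valued as `S * friction_period`, undiscounted —
#' friction periods are short (months), so discounting within the period is
#' deliberately omitted.
#'
#' @param S Annual income foregone (> 0).
#' @param fp A [friction_params()] object.
#' @return Lost output over the friction period, in the currency of `S`.
#' @examples
#' friction_cost_loss(5131.5, friction_params(0.25))
#' @export
friction_cost_loss <- function(S, fp) {
  check_scalar_number(S, "S")
  if (!inherits(fp, "friction_params"))
    stop_domain("`fp` must be a friction_params object")
  if (S <= 0) stop_domain("`S` must be > 0 (got %g)", S)
  S * fp$friction_period
}

#' Sensitivity sweep over discount rates and retirement ages
#'
#' Recomputes the national human-capital total over a grid of discount rates
#' and retirement ages, holding the death cohort structure fixed. Cohorts are
#' keyed by years to retirement under the base retirement age; raising the
#' retirement age by `d` years lengthens every remaining working lifespan by
#' `d` (the same individuals, retiring later). Each grid cell re-runs the
#' full per-person valuation and aggregation, so the cell matching the base
#' parameters equals the base total exactly.
#'
#' @param cohort_counts Named numeric vector mapping years-to-retirement `t`
#'   (under the base retirement age) to death counts.
#' @param base An [economic_params()] object supplying the income, base
#'   retirement age and base discount rate.
#' @param discount_rates Numeric vector of rates to sweep (each >= 0).
#' @param retirement_ages Integer vector of retirement ages to sweep.
#'
#' @return A tibble with columns `discount_rate`, `retirement_age` and
#'   `total_loss` (primary currency), one row per grid cell.
#' @examples
#' counts <- c(`40` = 3, `5` = 40)
#' sensitivity_sweep(counts, economic_params(),
#'                   discount_rates = c(0.03, 0.08, 0.12),
#'                   retirement_ages = c(55, 60))
#' @export
sensitivity_sweep <- function(cohort_counts, base,
                              discount_rates = base$discount_rate,
                              retirement_ages = base$retirement_age) {
  if (!inherits(base, "economic_params"))
    stop_domain("`base` must be an economic_params object")
  if (length(cohort_counts) == 0L)
    stop_domain("`cohort_counts` must be non-empty")
  if (is.null(names(cohort_counts)) || anyNA(suppressWarnings(as.numeric(names(cohort_counts)))))
    stop_domain("`cohort_counts` must be named by years-to-retirement")
  if (length(discount_rates) == 0L || length(retirement_ages) == 0L)
    stop_domain("sweep lists must be non-empty")
  if (any(discount_rates < 0))
    stop_domain("all discount rates must be >= 0 (got %g)", min(discount_rates))
  t0 <- as.numeric(names(cohort_counts))
  n <- as.numeric(cohort_counts)
  grid <- expand.grid(discount_rate = as.numeric(discount_rates),
                      retirement_age = as.numeric(retirement_ages),
                      KEEP.OUT.ATTRS = FALSE)
  grid$total_loss <- vapply(seq_len(nrow(grid)), function(i) {
    shift <- grid$retirement_age[i] - base$retirement_age
    t_eff <- pmax(t0 + shift, 0)
    sum(n * present_value_loss(base$annual_income, grid$discount_rate[i], t_eff))
  }, numeric(1))
  tibble::as_tibble(grid)
}
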