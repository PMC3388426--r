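#' Published reference inputs of the Fiji young-stroke mortality costing
#'
#' The national costing of young (working-age) stroke mortality in Fiji
#' reports its inputs as printed figures: per-cohort death counts, per-person
#' discounted output losses in thousands of F$, and the budget references the
#' total is compared against. These printed values are inputs to the
#' pipeline's "table-values" mode, in which per-person losses are carried
#' exactly as published rather than recomputed from the annuity formula (the
#' published per-person column is not reproduced by the stated formula
#' inputs; see the package vignette).
#'
#' @return `fiji_cohort_counts()`: named vector, deaths per years-to-
#'   retirement cohort (147 deaths over t = 40 down to 5).
#'   `fiji_per_person_loss()`: named vector, per-person discounted loss per
#'   cohort in thousands of F$.
#'   `fiji_reference_budgets()`: list of budget references, each with an
#'   `amount` in F$ and the decimal `digits` its published share uses.
#' @examples
#' sum(fiji_cohort_counts())  # 147 working-age stroke deaths
#' @name fiji_reference
NULL

#' @rdname fiji_reference
#' @export
fiji_cohort_counts <- function() {
  c(`40` = 3, `35` = 2, `30` = 9, `25` = 13, `20` = 16, `15` = 30,
    `10` = 34, `5` = 40)
}

#' @rdname fiji_reference
#' @export
fiji_per_person_loss <- function() {
  c(`40` = 140.4, `35` = 117.7, `30` = 114.9, `25` = 100.2, `20` = 83.9,
    `15` = 65.9, `10` = 46.1, `5` = 24.2)
}

#' @rdname fiji_reference
#' @export
fiji_reference_budgets <- function() {
  list(health_budget = list(amount = 91.02e6, digits = 1),
       government_revenue = list(amount = 895.99e6, digits = 0))
}
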