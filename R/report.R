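#' Assemble a national loss report from cohort counts and per-person values
#'
#' Multiplies each years-to-retirement cohort's death count by its per-person
#' discounted loss and sums to the national total, in both the primary and a
#' secondary reporting currency. Per-person values may come from
#' [present_value_loss()] ("formula mode") or be supplied as data exactly as
#' published ("table-values mode"). All money in the report is carried in
#' thousands of currency units at full precision; rounding happens only at
#' rendering.
#'
#' The secondary-currency total is the converted primary total (sum first,
#' convert after), so it matches published grand totals even where per-row
#' conversions round differently.
#'
#' @param cohort_counts Named numeric vector mapping years-to-retirement `t`
#'   to death counts, e.g. the output of [bin_to_cohorts()].
#' @param per_person Named numeric vector mapping `t` to the per-person
#'   discounted loss in thousands of primary currency units. Every populated
#'   cohort must be covered.
#' @param params An [economic_params()] object (supplies the exchange rate).
#' @return A `loss_report` object: a list with a `cohorts` tibble (columns
#'   `t`, `n`, `per_person`, `total`, ordered by decreasing `t`),
#'   `total_primary` and `total_secondary` (thousands), `cohort_shares`
#'   (exact percentages summing to 100), `budget_shares` (filled by
#'   [run_pipeline()]), and the `params` used.
#' @examples
#' counts <- c(`15` = 30)
#' aggregate_losses(counts, c(`15` = 65.9), economic_params())
#' @export
aggregate_losses <- function(cohort_counts, per_person, params) {
  stopifnot(inherits(params, "economic_params"))
  t <- as.numeric(names(cohort_counts))
  if (length(cohort_counts) > 0 && (is.null(names(cohort_counts)) || anyNA(t)))
    stop_domain("`cohort_counts` must be named by years-to-retirement")
  missing_pp <- setdiff(names(cohort_counts)[cohort_counts > 0], names(per_person))
  if (length(missing_pp) > 0)
    stop_config("no per-person value for populated cohort(s) t = %s",
                paste(missing_pp, collapse = ", "))
  ord <- order(t, decreasing = TRUE)
  t <- t[ord]
  n <- as.numeric(cohort_counts)[ord]
  pp <- as.numeric(per_person[as.character(t)])
  cohorts <- tibble::tibble(t = t, n = n, per_person = pp, total = n * pp)
  total_primary <- sum(cohorts$total)
  report <- structure(
    list(cohorts = cohorts,
         total_primary = total_primary,
         total_secondary = convert_currency(total_primary, params$exchange_rate),
         cohort_shares = NULL,
         budget_shares = numeric(0),
         params = params),
    class = "loss_report")
  if (total_primary > 0) report$cohort_shares <- cohort_shares(report)
  report
}

#' Convert an amount between currencies
#'
#' @param amount Amount in primary currency units (any scale).
#' @param rate Secondary-currency units per primary-currency unit (> 0).
#' @return `amount * rate`.
#' @examples
#' convert_currency(5131.50, 0.6)  # 3078.90
#' @export
convert_currency <- function(amount, rate) {
  check_scalar_number(rate, "rate")
  if (rate <= 0) stop_domain("`rate` must be > 0 (got %g)", rate)
  amount * rate
}

#' Percentage share of a whole
#'
#' `100 * part / whole`, rounded half-up to the requested number of decimal
#' places — the convention of published budget-share figures (so 0.9875
#' becomes 1 at zero decimals, not 0.99 banker's-rounded).
#'
#' @param part Non-negative amount, same units as `whole`.
#' @param whole Positive reference amount.
#' @param digits Decimal places of the returned percentage.
#' @return The rounded percentage.
#' @examples
#' share_of(8.8481e6, 91.02e6, digits = 1)   # 9.7
#' share_of(8.8481e6, 895.99e6, digits = 0)  # 1
#' @export
share_of <- function(part, whole, digits = 1) {
  check_scalar_number(part, "part")
  check_scalar_number(whole, "whole")
  if (whole <= 0) stop_domain("`whole` must be > 0 (got %g)", whole)
  if (part < 0) stop_domain("`part` must be >= 0 (got %g)", part)
  round_half_up(100 * part / whole, digits)
}

#' Cohort percentage shares of the national total
#'
#' Each cohort's share of the grand total, the quantity behind
#' "years to retirement versus percentage of total output loss" bar charts.
#' Shares are exact (unrounded) and sum to 100.
#'
#' @param report A `loss_report` from [aggregate_losses()].
#' @return Named numeric vector mapping `t` to its percentage share.
#' @export
cohort_shares <- function(report) {
  stopifnot(inherits(report, "loss_report"))
  if (report$total_primary <= 0)
    stop_domain("cohort shares are undefined for a zero grand total")
  stats::setNames(100 * report$cohorts$total / report$total_primary,
                  as.character(report$cohorts$t))
}

#' Render a loss report as a table
#'
#' Produces the published layout: one row per cohort with the number died,
#' years to retirement, per-person loss and total loss in both currencies
#' (thousands, one decimal place, half-up), and a final Total row. The
#' `"text"` format aligns columns and uses comma thousands separators
#' ("1,977.0"); the `"csv"` format emits plain machine-readable numbers that
#' re-parse to the same rounded values.
#'
#' @param report A `loss_report`.
#' @param format `"text"` (aligned, default) or `"csv"` (delimited).
#' @return A single string (text) or character vector of CSV lines.
#' @export
render_table <- function(report, format = c("text", "csv")) {
  stopifnot(inherits(report, "loss_report"))
  format <- match.arg(format)
  co <- report$cohorts
  rate <- report$params$exchange_rate
  rows <- data.frame(
    number_died = if (nrow(co)) as.integer(co$n) else integer(0),
    years_to_retirement = if (nrow(co)) as.integer(co$t) else integer(0),
    per_person_primary_000 = round_half_up(co$per_person, 1),
    per_person_secondary_000 = round_half_up(convert_currency(co$per_person, rate), 1),
    total_primary_000 = round_half_up(co$total, 1),
    total_secondary_000 = round_half_up(convert_currency(co$total, rate), 1))
  tot_p <- round_half_up(report$total_primary, 1)
  tot_s <- round_half_up(report$total_secondary, 1)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(c(out, sprintf("Total,,,,%s,%s",
                          formatC(tot_p, format = "f", digits = 1),
                          formatC(tot_s, format = "f", digits = 1))))
  }
  hdr <- c("Number died", "Years to retirement",
           "Per person (primary 000)", "Per person (secondary 000)",
           "Total (primary 000)", "Total (secondary 000)")
  body <- rbind(
    cbind(format(rows$number_died), format(rows$years_to_retirement),
          fmt_money(rows$per_person_primary_000),
          fmt_money(rows$per_person_secondary_000),
          fmt_money(rows$total_primary_000),
          fmt_money(rows$total_secondary_000)),
    c("Total", "", "", "", fmt_money(tot_p), fmt_money(tot_s)))
  widths <- pmax(nchar(hdr), apply(nchar(body), 2, max))
  pad <- function(x) paste(mapply(formatC, x, width = widths), collapse = "  ")
  paste(c(pad(hdr), apply(body, 1, pad)), collapse = "\n")
}

#' Parse a CSV-rendered loss table back into numbers
#'
#' Inverse of `render_table(format = "csv")`, used to verify that rendering
#' loses nothing beyond the stated one-decimal rounding.
#'
#' @param lines Character vector of CSV lines from [render_table()].
#' @return A data frame of the cohort rows (Total row dropped).
#' @export
parse_rendered_table <- function(lines) {
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  df[df[[1]] != "Total", , drop = FALSE]
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report>  human-capital output loss\n")
  cat(render_table(x), "\n")
  if (length(x$budget_shares) > 0) {
    cat("Budget shares:\n")
    for (nm in names(x$budget_shares))
      cat(sprintf("  %s: %g%%\n", nm, x$budget_shares[[nm]]))
  }
  invisible(x)
}

#' Bar chart of cohort shares
#'
#' Years to retirement against each cohort's percentage of the total output
#' loss, mirroring the standard presentation of human-capital mortality
#' costings.
#'
#' @param report A `loss_report`.
#' @return A ggplot object.
#' @export
plot_cohort_shares <- function(report) {
  shares <- cohort_shares(report)
  df <- data.frame(t = factor(as.numeric(names(shares))), share = as.numeric(shares))
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Years to retirement",
                  y = "Share of total output loss (%)") +
    ggplot2::theme_minimal()
}
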