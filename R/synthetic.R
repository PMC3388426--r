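#' Configuration for the synthetic mortality-record generator
#'
#' The generator emulates the structure of the national young-stroke
#' mortality data behind the Fiji costing: a year's deaths from one cause, a
#' known number falling inside the working-age window, and — in `"table"`
#' mode — exact per-cohort counts of years to retirement. Published costings
#' report cohort counts, not raw ages, so table mode draws each age uniformly
#' from the integer ages consistent with its cohort bin: any such choice
#' reproduces the downstream analysis exactly, and uniform is the
#' least-assuming.
#'
#' Defaults are the study conditions: 273 deaths of which 147 fall in the
#' 15--55 window, distributed over 5-year cohorts as 3, 2, 9, 13, 16, 30, 34,
#' 40 for t = 40 down to 5.
#'
#' @param mode `"table"` (exact cohort counts) or `"parametric"` (ages drawn
#'   from a distribution).
#' @param table_counts Named numeric vector mapping years-to-retirement
#'   cohort to death count (table mode).
#' @param total_deaths Total records to emit, in- plus out-of-window.
#' @param out_of_window_deaths Number of records with ages outside the
#'   working-age window (table mode; must satisfy
#'   `sum(table_counts) + out_of_window_deaths == total_deaths`).
#' @param out_of_window_fraction Probability that a record falls outside the
#'   window (parametric mode).
#' @param age_distribution Parametric mode: a list with `kind`
#'   (`"uniform"` or `"truncated-normal"`), `min`, `max`, and for the normal
#'   `mean` and `sd`, describing in-window ages.
#' @param bin_width Cohort width in years used to invert the binning rule.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `synthetic_config` object.
#' @examples
#' synthetic_config()                # the 273-death study structure
#' synthetic_config(mode = "parametric", total_deaths = 500,
#'                  out_of_window_fraction = 0.4)
#' @export
synthetic_config <- function(mode = c("table", "parametric"),
                             table_counts = c(`40` = 3, `35` = 2, `30` = 9,
                                              `25` = 13, `20` = 16, `15` = 30,
                                              `10` = 34, `5` = 40),
                             total_deaths = NULL,
                             out_of_window_deaths = 126,
                             out_of_window_fraction = 126 / 273,
                             age_distribution = list(kind = "uniform",
                                                     mean = 45, sd = 10,
                                                     min = 15, max = 55),
                             bin_width = 5,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (length(table_counts) > 0 && is.null(names(table_counts)))
      stop_config("`table_counts` must be named by years-to-retirement")
    if (any(table_counts < 0) || any(table_counts != round(table_counts)))
      stop_config("`table_counts` must be non-negative integers")
    if (is.null(total_deaths))
      total_deaths <- sum(table_counts) + out_of_window_deaths
    if (sum(table_counts) + out_of_window_deaths != total_deaths)
      stop_config("sum(table_counts) (%d) + out_of_window_deaths (%d) != total_deaths (%d)",
                  sum(table_counts), out_of_window_deaths, total_deaths)
  } else {
    if (is.null(total_deaths))
      stop_config("parametric mode requires `total_deaths`")
    if (out_of_window_fraction < 0 || out_of_window_fraction > 1)
      stop_config("`out_of_window_fraction` must be in [0, 1]")
    if (age_distribution$min >= age_distribution$max)
      stop_config("age distribution bounds must be ordered min < max")
  }
  structure(list(mode = mode,
                 table_counts = table_counts,
                 total_deaths = as.integer(total_deaths),
                 out_of_window_deaths = as.integer(out_of_window_deaths),
                 out_of_window_fraction = out_of_window_fraction,
                 age_distribution = age_distribution,
                 bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Ages outside the working-age window: elderly from [max+1, 90] and children
# from [1, min-1] in 9:1 proportion — out-of-window records never affect loss
# totals, only filter counts.
draw_out_of_window <- function(n, params) {
  if (n == 0L) return(integer(0))
  elder <- stats::runif(n) < 0.9
  age <- integer(n)
  age[elder] <- sample(seq(params$working_age_max + 1, 90), sum(elder),
                       replace = TRUE)
  age[!elder] <- sample(seq(1, params$working_age_min - 1), sum(!elder),
                        replace = TRUE)
  age
}

#' Generate synthetic mortality records
#'
#' Table mode emits, for each cohort `t` with count `n`, exactly `n` records
#' whose ages map back to bin `t` under the ceiling binning rule and the
#' given retirement age, plus the configured number of out-of-window records;
#' the full set is shuffled. Running the records through
#' [filter_working_age()] and [bin_to_cohorts()] recovers `table_counts`
#' exactly for any seed. Parametric mode draws each record out-of-window with
#' the configured probability and otherwise from the configured age
#' distribution.
#'
#' @param config A [synthetic_config()].
#' @param params An [economic_params()] object (window, retirement age).
#' @param cause Cause label written on every record.
#' @return A [mortality_records()] tibble of `config$total_deaths` rows.
#' @examples
#' rec <- generate_records(synthetic_config(seed = 7), economic_params())
#' nrow(rec)                                    # 273
#' nrow(filter_working_age(rec, economic_params()))  # 147
#' @export
generate_records <- function(config, params = economic_params(),
                             cause = "stroke") {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "economic_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  R <- params$retirement_age
  bw <- config$bin_width
  if (config$mode == "table") {
    ages <- integer(0)
    for (tc in names(config$table_counts)) {
      t_bin <- as.numeric(tc)
      n <- config$table_counts[[tc]]
      if (n == 0) next
      # bin t holds raw t in (t - bw, t], i.e. ages R - t .. R - t + bw - 1,
      # clipped to the working-age window and to ages strictly below R
      feas <- seq(R - t_bin, R - t_bin + bw - 1)
      feas <- feas[feas >= params$working_age_min &
                     feas <= params$working_age_max & feas < R]
      if (length(feas) == 0)
        stop_config("cohort t = %s has no feasible age under the window", tc)
      ages <- c(ages, feas[sample.int(length(feas), n, replace = TRUE)])
    }
    ages <- c(ages, draw_out_of_window(config$out_of_window_deaths, params))
  } else {
    n <- config$total_deaths
    out <- stats::runif(n) < config$out_of_window_fraction
    dist <- config$age_distribution
    draw_in <- function(k) {
      if (k == 0L) return(integer(0))
      if (identical(dist$kind, "uniform")) {
        sample(seq(dist$min, dist$max), k, replace = TRUE)
      } else {
        # truncated normal by rejection; ages recorded as completed years
        got <- integer(0)
        while (length(got) < k) {
          cand <- round(stats::rnorm(2L * (k - length(got)), dist$mean, dist$sd))
          got <- c(got, cand[cand >= dist$min & cand <= dist$max])
        }
        got[seq_len(k)]
      }
    }
    ages <- integer(n)
    ages[out] <- draw_out_of_window(sum(out), params)
    ages[!out] <- draw_in(sum(!out))
  }
  if (length(ages) > 0) ages <- ages[sample.int(length(ages))]
  mortality_records(age = ages, cause = cause)
}
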