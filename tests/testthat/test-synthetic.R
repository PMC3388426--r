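test_that("table-mode generation reproduces the study structure for any seed", {
  p <- fiji_params()
  for (seed in c(1, 99, 2026)) {
    rec <- generate_records(synthetic_config(seed = seed), p)
    expect_equal(nrow(rec), 273L)
    working <- filter_working_age(rec, p)
    expect_equal(nrow(working), 147L)
    bins <- bin_to_cohorts(working, p)
    expect_equal(bins[names(fiji_cohort_counts())],
                 setNames(as.integer(fiji_cohort_counts()),
                          names(fiji_cohort_counts())))
  }
})

test_that("generation is seed-deterministic down to the written file", {
  p <- fiji_params()
  a <- generate_records(synthetic_config(seed = 7), p)
  b <- generate_records(synthetic_config(seed = 7), p)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_mortality_records(a, fa)
  write_mortality_records(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different seed: different ages, same cohort counts
  c_ <- generate_records(synthetic_config(seed = 8), p)
  expect_false(identical(a$age, c_$age))
  expect_equal(bin_to_cohorts(filter_working_age(a, p), p),
               bin_to_cohorts(filter_working_age(c_, p), p))
})

test_that("generate -> filter -> bin round-trips arbitrary cohort count maps", {
  p <- fiji_params()
  set.seed(424242)
  for (i in 1:20) {
    ts <- sort(sample(seq(5, 40, by = 5), sample(2:8, 1)), decreasing = TRUE)
    counts <- setNames(sample(0:25, length(ts), replace = TRUE), ts)
    cfg <- synthetic_config(table_counts = counts,
                            out_of_window_deaths = sample(0:50, 1),
                            seed = sample.int(1e6, 1))
    rec <- generate_records(cfg, p)
    expect_equal(nrow(rec), cfg$total_deaths)
    bins <- bin_to_cohorts(filter_working_age(rec, p), p)
    nz <- counts[counts > 0]
    expect_equal(bins[order(as.numeric(names(bins)))],
                 setNames(as.integer(nz), names(nz))[order(as.numeric(names(nz)))])
  }
})

test_that("degenerate and inconsistent generator configs behave as contracted", {
  empty <- synthetic_config(table_counts = setNames(numeric(0), character(0)),
                            out_of_window_deaths = 0)
  expect_equal(nrow(generate_records(empty)), 0L)
  expect_error(
    synthetic_config(table_counts = c(`5` = 10), out_of_window_deaths = 5,
                     total_deaths = 20),
    class = "humcap_config_error")
  expect_error(synthetic_config(table_counts = c(`5` = -1)),
               class = "humcap_config_error")
  expect_error(synthetic_config(mode = "parametric"),
               class = "humcap_config_error")
  expect_error(
    synthetic_config(mode = "parametric", total_deaths = 10,
                     age_distribution = list(kind = "uniform", min = 50, max = 20)),
    class = "humcap_config_error")
})

test_that("parametric mode hits the configured in-window fraction at large n", {
  p <- fiji_params()
  cfg <- synthetic_config(mode = "parametric", total_deaths = 10000,
                          out_of_window_fraction = 126 / 273, seed = 5)
  rec <- generate_records(cfg, p)
  frac_in <- nrow(filter_working_age(rec, p)) / nrow(rec)
  expect_equal(frac_in, 147 / 273, tolerance = 0.02 / (147 / 273))
  # truncated-normal ages stay inside the stated bounds
  cfg2 <- synthetic_config(mode = "parametric", total_deaths = 500,
                           out_of_window_fraction = 0,
                           age_distribution = list(kind = "truncated-normal",
                                                   mean = 45, sd = 10,
                                                   min = 15, max = 55),
                           seed = 6)
  rec2 <- generate_records(cfg2, p)
  expect_true(all(rec2$age >= 15 & rec2$age <= 55))
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_records(synthetic_config(seed = 3)))
  expect_identical(.Random.seed, before)
})
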