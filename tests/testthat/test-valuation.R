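test_that("present value of foregone income matches frozen explicit-sum values", {
  # frozen from the independent oracle sum(S * 1.08^-(1:t))
  expect_equal(present_value_loss(5131.5, 0.08, 0), 0)
  expect_equal(present_value_loss(5131.5, 0.08, 5), 20488.5916, tolerance = 0.1 / 20488)
  expect_equal(present_value_loss(5131.5, 0.08, 40), 61191.1533, tolerance = 0.5 / 61191)
  expect_equal(present_value_loss(100, 0, 10), 1000)
})

test_that("closed form agrees with the explicit discounted sum to 1e-9 relative", {
  for (S in c(1, 5131.5)) {
    for (r in seq(0.01, 0.2, by = 0.01)) {
      pv <- present_value_loss(S, r, 0:45)
      oracle <- vapply(0:45, pv_oracle, numeric(1), S = S, r = r)
      expect_equal(pv, oracle, tolerance = 1e-9)
    }
  }
})

test_that("annuity is monotone: increasing in t and S, decreasing in r, bounded by S*t", {
  S <- 5131.5
  pv_t <- present_value_loss(S, 0.08, 0:45)
  expect_true(all(diff(pv_t) > 0))
  rs <- seq(0.01, 0.2, by = 0.01)
  pv_r <- vapply(rs, function(r) present_value_loss(S, r, 20), numeric(1))
  expect_true(all(diff(pv_r) < 0))
  expect_lt(present_value_loss(100, 0.08, 20), present_value_loss(200, 0.08, 20))
  # bounds: 0 <= PV <= S*t, right equality only at r = 0 or t = 0
  for (r in c(0, 0.05, 0.2)) {
    t <- 0:45
    pv <- present_value_loss(S, r, t)
    expect_true(all(pv >= 0))
    expect_true(all(pv <= S * t + 1e-9))
    eq <- abs(pv - S * t) < 1e-9 * pmax(S * t, 1)
    expect_equal(eq, r == 0 | t == 0)
  }
})

test_that("r -> 0 limit is continuous towards the undiscounted S*t", {
  for (t in c(1, 10, 45)) {
    expect_equal(present_value_loss(5131.5, 1e-12, t), 5131.5 * t,
                 tolerance = 1e-6)
  }
})

test_that("valuation rejects out-of-domain parameters by name", {
  expect_error(present_value_loss(-1, 0.08, 5), "`S`", class = "humcap_domain_error")
  expect_error(present_value_loss(100, -0.01, 5), "`r`", class = "humcap_domain_error")
  expect_error(present_value_loss(100, 0.08, -1), "`t`", class = "humcap_domain_error")
})

test_that("friction-cost loss is income times friction period, undiscounted", {
  expect_equal(friction_cost_loss(5131.5, friction_params(0)), 0)
  expect_equal(friction_cost_loss(5131.5, friction_params(0.25)), 1282.875)
  expect_equal(friction_cost_loss(5131.5, friction_params(1.0)), 5131.5)
  expect_error(friction_params(-0.1), class = "humcap_domain_error")
  expect_error(friction_params(0.25, unemployment_rate = 1.5),
               class = "humcap_domain_error")
  # far below the human-capital value for any worker with years to retirement
  expect_lt(friction_cost_loss(5131.5, friction_params(0.5)),
            present_value_loss(5131.5, 0.08, 5))
})

test_that("sensitivity sweep reproduces the base cell exactly and re-runs the valuation", {
  counts <- fiji_cohort_counts()
  base <- fiji_params()
  base_total <- sum(counts * present_value_loss(base$annual_income,
                                                base$discount_rate,
                                                as.numeric(names(counts))))
  one <- sensitivity_sweep(counts, base, discount_rates = 0.08,
                           retirement_ages = 55)
  expect_equal(nrow(one), 1L)
  expect_identical(one$total_loss, base_total)

  # oracle: three independent explicit-sum aggregations, strictly decreasing in r
  rates <- c(0.03, 0.08, 0.12)
  sw <- sensitivity_sweep(counts, base, discount_rates = rates,
                          retirement_ages = 55)
  oracle <- vapply(rates, function(r)
    sum(vapply(names(counts), function(tc)
      counts[[tc]] * pv_oracle(base$annual_income, r, as.numeric(tc)),
      numeric(1))), numeric(1))
  expect_equal(sw$total_loss[order(sw$discount_rate)],
               oracle[order(rates)], tolerance = 1e-9)
  expect_true(all(diff(sw$total_loss[order(sw$discount_rate)]) < 0))

  # later retirement lengthens every horizon by 5 years: total must rise
  sw2 <- sensitivity_sweep(counts, base, discount_rates = 0.08,
                           retirement_ages = c(55, 60))
  tot <- sw2$total_loss[order(sw2$retirement_age)]
  expect_gt(tot[2], tot[1])
  oracle60 <- sum(vapply(names(counts), function(tc)
    counts[[tc]] * pv_oracle(base$annual_income, 0.08, as.numeric(tc) + 5),
    numeric(1)))
  expect_equal(tot[2], oracle60, tolerance = 1e-9)

  expect_error(sensitivity_sweep(counts, base, discount_rates = c(0.08, -0.01)),
               class = "humcap_domain_error")
  expect_error(sensitivity_sweep(setNames(numeric(0), character(0)), base),
               class = "humcap_domain_error")
})

test_that("economic parameter construction enforces its invariants", {
  expect_error(economic_params(annual_income = 0), class = "humcap_domain_error")
  expect_error(economic_params(discount_rate = -0.08), class = "humcap_domain_error")
  expect_error(economic_params(exchange_rate = 0), class = "humcap_domain_error")
  expect_error(economic_params(working_age_min = 60),
               class = "humcap_domain_error")
  expect_error(economic_params(working_age_max = 70),
               class = "humcap_domain_error")
  p <- economic_params(discount_rate = 0)
  expect_s3_class(p, "economic_params")
  expect_equal(p$working_age_max, 55)
})
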