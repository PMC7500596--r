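test_that("required events match direct evaluation of the log-rank formula", {
  # frozen normal quantiles computed independently: qnorm(0.975), qnorm(0.90),
  # qnorm(0.80) = 1.959964, 1.281552, 0.841621
  n0 <- events_required(testing_spec(0.05, 0.90, 0.8))
  expect_equal(n0, 4 * (1.959964 + 1.281552)^2 / log(0.8)^2, tolerance = 1e-6)
  expect_equal(n0, 844.1, tolerance = 1e-4)

  expect_equal(events_required(testing_spec(0.05, 0.80, 0.5)),
               65.3, tolerance = 1e-3)
  expect_error(testing_spec(treatment_hr = 1), "infeasible")
})

test_that("fixed-duration event rates and the delta-method SD evaluate correctly", {
  r <- event_rates_fixed(1, 0, treatment_hr = 0.8)
  expect_equal(r$p_control, 0)
  expect_equal(r$p_treatment, 0)

  r <- event_rates_fixed(0.83, 0.01, treatment_hr = 0.8)
  expect_equal(r$p_control, 0.17)
  expect_equal(r$p_treatment, 1 - 0.83^0.8)
  expect_equal(r$p_treatment, 0.1385, tolerance = 1e-3)
  expect_equal(r$sd_p, (1 + 0.8 * 0.83^(-0.2)) * 0.01)
  expect_equal(r$sd_p, 0.0183, tolerance = 1e-3)
  expect_lte(r$p_treatment, r$p_control)  # HR < 1 can only reduce events
})

test_that("delta-method slope matches numeric differentiation of p(S)", {
  h <- 1e-6
  for (S in c(0.5, 0.8, 0.95)) {
    for (HR in c(0.5, 0.8)) {
      p_of_s <- function(s) (1 - s) + (1 - s^HR)
      num <- abs(p_of_s(S + h) - p_of_s(S - h)) / (2 * h)
      ana <- 1 + HR * S^(HR - 1)
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("Simpson accrual rates match hand computation on exponential survival", {
  lambda <- -log(0.82) / 48
  tms <- seq(0.5, 48, by = 0.5)   # grid contains 36, 42, 48 exactly
  curve <- survenrich:::new_survival_curve(
    times = tms, surv = exp(-lambda * tms), se = rep(0, length(tms)),
    n_risk = NA, n_event = NA, method = "KM", threshold = 0, tmax = 48, n = 1)

  r <- event_rates_accrual(curve, accrual = 12, followup = 36,
                           treatment_hr = 0.8)
  hand <- 1 - (exp(-36 * lambda) + 4 * exp(-42 * lambda) +
                 exp(-48 * lambda)) / 6
  expect_equal(r$p_control, hand, tolerance = 1e-12)
  expect_lt(abs(r$p_control - 0.1593), 5e-5)   # agrees to 4 decimals

  # Simpson approximates the exact uniform-entry average (1/a) int F(u) du
  exact <- 1 - (exp(-36 * lambda) - exp(-48 * lambda)) / (12 * lambda)
  expect_equal(r$p_control, exact, tolerance = 1e-3)

  # rate sits between the fixed-duration rates at f and f + a
  expect_gt(r$p_control, 1 - exp(-36 * lambda))
  expect_lt(r$p_control, 1 - exp(-48 * lambda))

  # zero accrual degenerates to the fixed-duration rate at f
  r0 <- event_rates_accrual(curve, accrual = 0, followup = 36,
                            treatment_hr = 0.8)
  expect_equal(r0$p_control, 1 - exp(-36 * lambda), tolerance = 1e-12)

  flat <- survenrich:::new_survival_curve(
    times = 48, surv = 1, se = 0, n_risk = NA, n_event = NA,
    method = "KM", threshold = 0, tmax = 48, n = 1)
  expect_equal(event_rates_accrual(flat, 12, 36, 0.8)$p_control, 0)
  expect_error(event_rates_accrual(curve, accrual = 24, followup = 36,
                                   treatment_hr = 0.8), "beyond")
})

test_that("sample size follows N = 2 N0 / (pC + pT) with the delta-method SD", {
  rates <- structure(list(p_control = 0.17, p_treatment = 0.1385,
                          p_sum = 0.3085, sd_p = 0.0183,
                          sd_p_control = 0.01),
                     class = "event_rate_estimate")
  s <- sample_size(844.1, rates)
  expect_equal(s$total_n, 2 * 844.1 / 0.3085)
  expect_equal(s$total_n_display, 5472)
  expect_equal(s$sd_n, (2 * 844.1 / 0.3085^2) * 0.0183)
  expect_equal(s$sd_n, 325, tolerance = 1e-2)
  # solving back: N (pC + pT) / 2 = N0
  expect_equal(s$total_n * rates$p_sum / 2, 844.1)

  # everyone events: N = N0
  all_ev <- structure(list(p_control = 1, p_treatment = 1, p_sum = 2,
                           sd_p = 0, sd_p_control = 0),
                      class = "event_rate_estimate")
  expect_equal(sample_size(844.1, all_ev)$total_n, 844.1)

  # N is decreasing in the summed event rate and never below N0
  ns <- sapply(seq(0.05, 2, by = 0.05), function(p) {
    r <- structure(list(p_sum = p, sd_p = 0), class = "event_rate_estimate")
    sample_size(100, r)$total_n
  })
  expect_true(all(diff(ns) < 0))
  expect_true(all(ns >= 100))

  none <- structure(list(p_sum = 0, sd_p = 0), class = "event_rate_estimate")
  expect_error(sample_size(100, none), "infinite")
})

test_that("screening totals and costs follow the stated formulas", {
  expect_equal(total_screened(3320, 0.50), 6640)
  expect_equal(total_screened(2360, 0.75), 9440)
  expect_equal(total_screened(1234.5, 0), 1234.5)
  expect_error(total_screened(100, 1), "\\[0, 1\\)")
  # identity before display rounding
  for (t in seq(0, 0.9, by = 0.1))
    expect_equal(total_screened(777.7, t) * (1 - t), 777.7)

  cs <- cost_spec(100, trial_cost = 1000)
  expect_equal(total_cost(1000, 0.5, cs), 1e6 + 100 * 2000)
  expect_equal(total_cost(1000, 0.9, cost_spec(0, trial_cost = 1000)), 1e6)

  ct <- cost_spec(0, cost_per_time = 100)
  expect_equal(total_cost(1000, 0.5, ct, expected_time_in_trial = 40), 4e6)
  expect_error(total_cost(1000, 0.5, ct), "expected_time_in_trial")
  expect_error(cost_spec(100, trial_cost = 1, cost_per_time = 1),
               "exactly one")

  expect_equal(cost_reduction(2e6, 2e6), 0)
  expect_equal(cost_reduction(1.5e6, 2e6), 25)
  expect_equal(cost_reduction(2.2e6, 2e6), -10)
})

test_that("bootstrap SEs are reproducible and vanish for degenerate data", {
  d <- sim_example2(seed = 4, n = 300)
  des <- accrual_design(12, 36)
  ts <- testing_spec()
  se1 <- bootstrap_se(d, des, ts, 0.25, "event_rate", B = 60, seed = 99)
  se2 <- bootstrap_se(d, des, ts, 0.25, "event_rate", B = 60, seed = 99)
  expect_identical(se1, se2)
  expect_gt(se1, 0)

  cens <- biomarker_survival_data(rnorm(40), rep(36, 40), rep(0, 40))
  expect_equal(bootstrap_se(cens, fixed_design(36), ts, 0, "event_rate",
                            B = 50, seed = 1), 0)
})
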