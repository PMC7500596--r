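testing <- testing_spec(0.05, 0.90, 0.8)

test_that("the unenriched row equals the direct whole-sample computation", {
  d <- sim_example2(seed = 6, n = 1000)
  tab <- analyze(d, fixed_design(36), testing, grid = c(0, 0.5), B = 0)
  row0 <- tab$table[1, ]

  s <- survival_at(kaplan_meier(d), 36)
  rates <- event_rates_fixed(s$surv, s$se, 0.8)
  size <- sample_size(events_required(testing), rates)
  expect_equal(row0$event_rate_pct_exact, 100 * rates$p_control)
  expect_equal(row0$sample_size_exact, size$total_n)
  expect_equal(row0$sample_size_se, size$sd_n)
  expect_equal(row0$total_screened_exact, size$total_n)
})

test_that("a single-threshold grid yields the baseline design", {
  d <- sim_example2(seed = 23, n = 500)
  tab <- analyze(d, fixed_design(36), testing, grid = 0,
                 costs = cost_spec(500, trial_cost = 4000), B = 0)
  expect_equal(nrow(tab$table), 1)
  expect_equal(tab$table$total_screened_exact, tab$table$sample_size_exact)
  expect_equal(tab$table$cost_reduction_pct, 0)
})

test_that("configuration contracts are enforced", {
  d <- sim_example2(seed = 23, n = 500)
  expect_error(analyze(d, accrual_design(12, 36), testing, estimator = "nne"),
               "Kaplan-Meier")
  expect_error(analyze(d, fixed_design(36), testing, grid = c(0.25, 0.5)),
               "include the unenriched")
  expect_error(analyze(d, fixed_design(36), testing, grid = c(0, 0.97)),
               "0.95")
  tiny <- sim_example2(seed = 1, n = 10)
  expect_error(analyze(tiny, fixed_design(36), testing), "floor")
})

test_that("the analysis is deterministic given a seed, including bootstrap SEs", {
  d <- sim_example2(seed = 30, n = 400)
  run <- function() analyze(d, accrual_design(12, 36), testing,
                            grid = c(0, 0.25, 0.5), B = 60, seed = 5)
  t1 <- run(); t2 <- run()
  expect_identical(t1$table, t2$table)
  expect_true(all(t1$table$event_rate_se > 0))

  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_enrichment_table(t1, p1); write_enrichment_table(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("analysis is invariant to biomarker orientation", {
  d <- sim_example2(seed = 44, n = 400)
  flipped <- biomarker_survival_data(-d$data$biomarker, d$data$time,
                                     d$data$event, higher_is_riskier = FALSE)
  t1 <- analyze(d, fixed_design(36), testing, grid = seq(0, 0.8, 0.2), B = 0)
  t2 <- analyze(flipped, fixed_design(36), testing, grid = seq(0, 0.8, 0.2),
                B = 0)
  expect_equal(t1$table, t2$table)
})

test_that("event rate increases with enrichment for a prognostic marker", {
  d <- sim_example2(seed = 3)
  tab <- analyze(d, fixed_design(48), testing, B = 0)
  rate <- tab$table$event_rate_pct_exact
  expect_true(all(diff(rate) > -1))   # non-decreasing up to 1 point of noise
  expect_gt(rate[19] - rate[1], 20)   # strong marker: large overall climb
  # screening burden never below the sample size; equality only at t = 0
  expect_true(all(tab$table$total_screened_exact >=
                    tab$table$sample_size_exact))
  expect_equal(tab$table$total_screened_exact[1],
               tab$table$sample_size_exact[1])
})

test_that("time-dependent costs use the restricted mean time in trial", {
  d <- sim_example2(seed = 9, n = 600)
  costs <- cost_spec(300, cost_per_time = 100)
  tab <- analyze(d, accrual_design(12, 36), testing, costs = costs,
                 grid = c(0, 0.5), B = 0)
  row <- tab$table[2, ]
  curve <- tab$curves[[2]]
  rm_arm <- function(h) (survenrich:::rmst_step(curve$times, curve$surv, h) +
                           survenrich:::rmst_step(curve$times, curve$surv^0.8, h)) / 2
  etime <- sum(c(1, 4, 1) / 6 * sapply(36 + c(0, 6, 12), rm_arm))
  expect_equal(row$expected_time_in_trial, etime)
  expect_equal(row$total_cost,
               100 * etime * row$sample_size_exact + 300 * row$total_screened_exact)
  # expected time in trial cannot exceed the longest observation
  expect_true(all(tab$table$expected_time_in_trial <= 48))
})

test_that("render_outputs writes the table, run log and optional figure", {
  d <- sim_example2(seed = 2, n = 400)
  tab <- analyze(d, fixed_design(36), testing, grid = seq(0, 0.75, 0.25),
                 costs = cost_spec(500, trial_cost = 4000), B = 0)
  dir <- withr::local_tempdir()
  paths <- render_outputs(tab, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "results_run.json")))
  expect_false(file.exists(file.path(dir, "results.png")))
  back <- read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(back), 4)

  log <- jsonlite::read_json(file.path(dir, "results_run.json"))
  expect_equal(log$metadata$estimator, "KM")
  expect_equal(log$testing$power, 0.9)

  paths <- render_outputs(tab, dir, make_figures = TRUE)
  expect_true(file.exists(file.path(dir, "results.png")))

  # subgroup curves used for plotting are ordered: higher threshold, lower survival
  s36 <- sapply(tab$curves, function(cv) survival_at(cv, 36)$surv)
  expect_true(all(diff(s36) < 0))
})
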