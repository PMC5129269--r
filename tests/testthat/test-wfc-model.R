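test_that("default tables encode the workload schedule and experience ramp", {
  tabs <- default_tables()
  expect_equal(evaluate_lookup(tabs$workload, 0), 6)
  expect_equal(evaluate_lookup(tabs$workload, 20), 8)
  expect_equal(evaluate_lookup(tabs$workload, c(2, 6, 10, 15, 25, 36)),
               c(6, 9, 12, 12, 8, 8))
  expect_equal(evaluate_lookup(tabs$job_experience, c(0, 9, 36)),
               c(0.5, 0.55, 0.7))

  flat <- default_tables(params = wfc_parameters(je_start = 0.5, je_end = 0.5))
  expect_equal(evaluate_lookup(flat$job_experience, c(0, 7, 36, 80)),
               rep(0.5, 4))
})

test_that("work chain reproduces the hand-evaluated project-start values", {
  w <- work_chain(5, 5, 6, 0.5)
  expect_equal(w$working_time, 6)
  expect_equal(w$job_involvement, 30)
  expect_equal(w$job_performance, 45)
  expect_equal(w$organizational_support, 4.5)
  expect_equal(w$job_pressure, 6 / 202.5, tolerance = 1e-12)
  expect_equal(w$wifc, 2 / 45, tolerance = 1e-12)

  # WIFC scales as 1/WF^2: through job pressure and the explicit divisor
  w5 <- work_chain(5, 5, 6, 0.5, wfc_parameters(work_flexibility = 5))
  expect_equal(w5$wifc, w$wifc / 25, tolerance = 1e-12)

  # vanishing job satisfaction drives the guarded job-pressure denominator down
  expect_error(work_chain(1e-6, 1e-6, 6, 0.5),
               "job pressure")
})

test_that("family chain reproduces the hand-evaluated project-start values", {
  f <- family_chain(1.5, 1.5, 6)
  expect_equal(f$family_involvement, 25)
  expect_equal(f$family_support, 25)
  expect_equal(f$family_performance, 3.75)
  expect_equal(f$family_pressure, 1 / 93.75, tolerance = 1e-12)
  expect_equal(f$fiwc, 1 / 75, tolerance = 1e-12)

  # doubling the family-support gain exactly halves FIWC (states fixed)
  f2 <- family_chain(1.5, 1.5, 6, wfc_parameters(family_support_gain = 2))
  expect_equal(f2$fiwc, f$fiwc / 2, tolerance = 1e-12)

  # doubling working time halves family involvement
  f3 <- family_chain(1.5, 1.5, 12)
  expect_equal(f3$family_involvement, f$family_involvement / 2)
})

test_that("satisfaction increments erode each domain by the opposing conflict", {
  unit <- wfc_parameters(js_decay_gain = 1, fs_decay_gain = 1)
  inc <- satisfaction_increments(2 / 45, 1 / 75, unit)
  expect_equal(inc$job_satisfaction_increment, -1 / 75, tolerance = 1e-12)
  expect_equal(inc$family_satisfaction_increment, -2 / 45, tolerance = 1e-12)

  zero <- satisfaction_increments(0, 0, unit)
  expect_equal(zero$job_satisfaction_increment, 0)
  expect_equal(zero$family_satisfaction_increment, 0)

  double <- satisfaction_increments(2 / 45, 1 / 75,
                                    wfc_parameters(js_decay_gain = 2,
                                                   fs_decay_gain = 1))
  expect_equal(double$job_satisfaction_increment,
               2 * inc$job_satisfaction_increment)
})

test_that("the assembled model matches the diagram structure", {
  model <- build_wfc_model()
  roles <- variable_roles(model)
  expect_equal(sum(roles != "delay"), 18L)
  expect_equal(sum(roles == "stock"), 2L)
  expect_equal(sum(roles == "rate"), 2L)
  expect_equal(sum(roles %in% c("auxiliary", "lookup")), 13L)
  expect_equal(sum(roles == "constant"), 1L)
  expect_equal(sum(roles == "delay"), 2L)
  expect_equal(model$variables$job_satisfaction$initial_value, 5)
  expect_equal(model$variables$family_satisfaction$initial_value, 1.5)
  expect_equal(model$variables$delayed_job_satisfaction$delay_time, 1)

  # instantaneous subgraph is acyclic: a valid order exists
  g <- build_dependency_graph(model)
  expect_no_error(instantaneous_order(g))

  # the four loops read off the causal-loop diagram are all present
  loops <- enumerate_feedback_loops(g, collapse_delays = TRUE,
                                    delay_inputs = delay_inputs(model))
  for (l in wfc_printed_loops()) expect_true(has_loop(loops, l))
})

test_that("model equations agree with the standalone chain algebra at start", {
  traj <- run_model(build_wfc_model(), simulation_config(horizon = 1))
  row0 <- traj$series[1, ]
  w <- work_chain(5, 5, 6, 0.5)
  f <- family_chain(1.5, 1.5, w$working_time)
  for (v in names(w)) expect_equal(row0[[v]], w[[v]], tolerance = 1e-12)
  for (v in names(f)) expect_equal(row0[[v]], f[[v]], tolerance = 1e-12)
  inc <- satisfaction_increments(w$wifc, f$fiwc)
  expect_equal(row0$job_satisfaction_increment,
               inc$job_satisfaction_increment, tolerance = 1e-12)
  expect_equal(row0$family_satisfaction_increment,
               inc$family_satisfaction_increment, tolerance = 1e-12)
})

test_that("scenario presets and override validation", {
  expect_identical(make_scenario("current")$overrides, list())
  expect_equal(make_scenario("current_1")$overrides,
               list(work_flexibility = 5))
  expect_equal(make_scenario("current_2")$overrides,
               list(family_support_gain = 2))
  expect_equal(make_scenario("current_3")$overrides,
               list(org_support_gain = 0.3))
  expect_error(make_scenario("current_9"), "current_1")
  expect_error(scenario_spec("x", list(not_a_parameter = 1)),
               "not_a_parameter")

  p <- apply_scenario(wfc_parameters(), "current_1")
  expect_equal(p$work_flexibility, 5)
  expect_equal(p$js0, 5)

  expect_error(wfc_parameters(perf_divisor = 0), "perf_divisor")
  expect_error(wfc_parameters(je_end = 0.4), "je_end")
})
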