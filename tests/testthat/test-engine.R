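test_that("a zero-rate stock is conserved bitwise", {
  traj <- run_model(single_stock_model(rate_value = 0, initial = 1.7),
                    simulation_config(horizon = 10, dt = 0.25))
  expect_identical(traj$series$level, rep(1.7, length(traj$times)))
})

test_that("Euler integration converges to the closed-form exponential decay", {
  max_err <- function(dt) {
    traj <- run_model(decay_model(), simulation_config(horizon = 5, dt = dt))
    max(abs(traj$series$level - exp(-traj$times)))
  }
  dts <- c(0.1, 0.05, 0.025)
  errs <- vapply(dts, max_err, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_true(all(errs < 1.0 * dts))
})

test_that("recording grid and config validation behave as specified", {
  cfg <- simulation_config(horizon = 36, save_every = 0.5)
  traj <- run_model(build_wfc_model(), cfg)
  expect_length(traj$times, 36 / 0.5 + 1)
  expect_true(all(diff(traj$times) > 0))
  expect_true(all(is.finite(as.matrix(traj$series))))
  # first recorded value of the job-satisfaction stock is its initial value
  expect_identical(traj$series$job_satisfaction[1], 5)

  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(horizon = -1), "horizon")
  expect_error(simulation_config(dt = 0.0625, save_every = 0.1),
               "integer multiple")
})

test_that("default-model stock trajectories are step-halving convergent", {
  full <- run_model(build_wfc_model(), simulation_config(dt = 0.0625,
                                                         save_every = 0.5))
  half <- run_model(build_wfc_model(), simulation_config(dt = 0.03125,
                                                         save_every = 0.5))
  for (v in c("job_satisfaction", "family_satisfaction")) {
    rel <- abs(full$series[[v]] - half$series[[v]]) / abs(half$series[[v]])
    expect_lt(max(rel), 0.01)
  }
})

test_that("guarded divisions abort with the variable name and time", {
  m <- sd_model(list(
    sd_variable("shrinking", "rate", equation = quote(-1 + 0 * level),
                dependencies = "level"),
    sd_variable("level", "stock", initial_value = 1, rates = "shrinking"),
    sd_variable("inverse", "auxiliary", equation = quote(qdiv(1, level)))),
    name = "guard_demo")
  err <- tryCatch(run_model(m, simulation_config(horizon = 3, dt = 0.25)),
                  error = identity)
  expect_s3_class(err, "wfcsim_numerical_error")
  expect_match(conditionMessage(err), "inverse")
  expect_match(conditionMessage(err), "t = 1")
  expect_equal(err$variable, "inverse")
})

test_that("non-finite equation values abort with diagnostics", {
  m <- sd_model(list(
    sd_variable("bad", "auxiliary", equation = quote(sqrt(level - 2)),
                dependencies = "level"),
    sd_variable("zero", "rate", equation = quote(0 * level),
                dependencies = "level"),
    sd_variable("level", "stock", initial_value = 1, rates = "zero")),
    name = "nan_demo")
  expect_error(suppressWarnings(run_model(m, simulation_config(horizon = 1,
                                                               dt = 0.5))),
               "non-finite.*'bad'|'bad'.*non-finite")
})

test_that("stocks may go negative with a one-time warning; clamping floors them", {
  m <- single_stock_model(rate_value = -1, initial = 0.5)
  expect_warning(traj <- run_model(m, simulation_config(horizon = 2, dt = 0.25)),
                 "crossed zero")
  expect_lt(min(traj$series$level), 0)
  suppressWarnings(
    clamped <- run_model(m, simulation_config(horizon = 2, dt = 0.25,
                                              clamp_stocks_at_zero = TRUE)))
  expect_identical(min(clamped$series$level), 0)
})

test_that("identical runs are bit-identical (fully deterministic engine)", {
  a <- run_model(build_wfc_model(), simulation_config(horizon = 9))
  b <- run_model(build_wfc_model(), simulation_config(horizon = 9))
  expect_identical(a$series, b$series)
  expect_identical(a$times, b$times)
})
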