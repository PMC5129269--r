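#' Simulation configuration
#'
#' Fixed-grid settings for the explicit Euler integrator. The defaults match
#' the model's study conditions: a 36-month horizon on a 0.0625-month step,
#' recording every step.
#'
#' @param t0 start time, months.
#' @param horizon end time, months; must exceed `t0`.
#' @param dt integration step, months, > 0; `(horizon - t0)` must be an
#'   integer number of steps.
#' @param save_every recording interval, months; an integer multiple of `dt`.
#' @param guard_epsilon denominators of guarded divisions smaller in
#'   magnitude than this abort the run with a named error.
#' @param clamp_stocks_at_zero if `TRUE`, stocks are floored at zero after
#'   each step instead of going negative. Off by default; a one-time warning
#'   is emitted when any stock first crosses zero.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(t0 = 0, horizon = 36, dt = 0.0625,
                              save_every = dt, guard_epsilon = 1e-9,
                              clamp_stocks_at_zero = FALSE) {
  stopifnot(is.numeric(t0), is.numeric(horizon), is.numeric(dt),
            is.numeric(save_every), is.numeric(guard_epsilon))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (horizon <= t0) stop("`horizon` must exceed `t0`", call. = FALSE)
  steps <- (horizon - t0) / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop("(horizon - t0) must be an integer number of steps of size `dt`",
         call. = FALSE)
  m <- save_every / dt
  if (save_every <= 0 || abs(m - round(m)) > 1e-8)
    stop("`save_every` must be a positive integer multiple of `dt`", call. = FALSE)
  structure(list(t0 = t0, horizon = horizon, dt = dt, save_every = save_every,
                 guard_epsilon = guard_epsilon,
                 clamp_stocks_at_zero = isTRUE(clamp_stocks_at_zero)),
            class = "simulation_config")
}

.numerical_error <- function(variable, time, detail) {
  stop(structure(
    class = c("wfcsim_numerical_error", "error", "condition"),
    list(message = sprintf("numerical domain error in '%s' at t = %g: %s",
                           variable, time, detail),
         call = NULL, variable = variable, time = time)))
}

#' Run a stock-and-flow simulation
#'
#' Explicit Euler integration on a fixed grid. At each step the auxiliary,
#' lookup and rate equations are evaluated in [instantaneous_order()] from
#' the current stock, delay and constant values; the stocks and delay states
#' then advance by `dt`. Rows are recorded every `save_every` months,
#' including both endpoints. Any guarded division (`qdiv`) whose denominator
#' falls below `guard_epsilon` in magnitude, and any non-finite value, aborts
#' with an error naming the variable and the time.
#'
#' @param model an [sd_model()].
#' @param config a [simulation_config()].
#' @param scenario_name label stored on the trajectory.
#' @return an object of class `sd_trajectory`: a list with `times`, `series`
#'   (data frame, one alphabetically ordered column per variable), `config`,
#'   `scenario_name` and `model_name`.
#' @export
run_model <- function(model, config = simulation_config(),
                      scenario_name = "default") {
  stopifnot(inherits(model, "sd_model"), inherits(config, "simulation_config"))
  vars <- model$variables
  order <- instantaneous_order(build_dependency_graph(model))
  roles <- variable_roles(model)
  algebraic <- order[roles[order] %in% c("auxiliary", "rate", "lookup")]

  stocks <- names(roles)[roles == "stock"]
  delays <- names(roles)[roles == "delay"]
  consts <- names(roles)[roles == "constant"]

  n_steps <- as.integer(round((config$horizon - config$t0) / config$dt))
  stride <- as.integer(round(config$save_every / config$dt))
  n_saved <- n_steps %/% stride + 1L

  all_names <- sort(names(vars))
  out <- matrix(NA_real_, n_saved, length(all_names),
                dimnames = list(NULL, all_names))
  times <- numeric(n_saved)

  # evaluation environment: current values as variables, plus the guarded
  # division; .guard_var / .guard_t carry context for error reporting
  eps <- config$guard_epsilon
  env <- new.env(parent = baseenv())
  env$qdiv <- function(num, den) {
    if (abs(den) < eps)
      .numerical_error(get(".guard_var", envir = env),
                       get(".guard_t", envir = env),
                       sprintf("denominator %g below guard epsilon %g", den, eps))
    num / den
  }
  for (k in consts) assign(k, vars[[k]]$value, envir = env)

  state_stock <- vapply(vars[stocks], `[[`, numeric(1), "initial_value")
  state_delay <- vapply(vars[delays], `[[`, numeric(1), "initial_value")
  warned_negative <- FALSE

  for (step in 0:n_steps) {
    t <- config$t0 + step * config$dt
    assign("time", t, envir = env)
    assign(".guard_t", t, envir = env)
    for (k in stocks) assign(k, state_stock[[k]], envir = env)
    for (k in delays) assign(k, state_delay[[k]], envir = env)

    for (k in algebraic) {
      v <- vars[[k]]
      assign(".guard_var", k, envir = env)
      val <- if (v$role == "lookup") {
        evaluate_lookup(v$table,
                        if (identical(v$input, "time")) t else get(v$input, envir = env))
      } else {
        eval(v$equation, envir = env)
      }
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
        .numerical_error(k, t, "equation produced a non-finite value")
      assign(k, val, envir = env)
    }

    if (step %% stride == 0L) {
      i <- step %/% stride + 1L
      times[i] <- t
      out[i, ] <- vapply(all_names, get, numeric(1), envir = env)
    }
    if (step == n_steps) break

    for (k in stocks) {
      rate_sum <- sum(vapply(vars[[k]]$rates, get, numeric(1), envir = env))
      state_stock[[k]] <- state_stock[[k]] + config$dt * rate_sum
    }
    if (any(state_stock < 0)) {
      if (!warned_negative) {
        warned_negative <- TRUE
        warning("stock(s) ", paste(names(state_stock)[state_stock < 0], collapse = ", "),
                " crossed zero at t = ", t + config$dt,
                if (config$clamp_stocks_at_zero) " (clamped)" else "",
                call. = FALSE)
      }
      if (config$clamp_stocks_at_zero) state_stock <- pmax(state_stock, 0)
    }
    for (k in delays) {
      v <- vars[[k]]
      state_delay[[k]] <- delay1_update(state_delay[[k]],
                                        get(v$input, envir = env),
                                        v$delay_time, config$dt)
    }
  }

  structure(list(times = times,
                 series = as.data.frame(out),
                 config = config,
                 scenario_name = scenario_name,
                 model_name = model$name),
            class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat("<sd_trajectory> '", x$scenario_name, "' on model '", x$model_name,
      "': ", length(x$times), " rows x ", ncol(x$series),
      " variables, t in [", x$times[1L], ", ", x$times[length(x$times)],
      "] months\n", sep = "")
  invisible(x)
}

#' Extract one series from a trajectory
#'
#' @param traj an [run_model()] trajectory.
#' @param variable variable name.
#' @return numeric vector aligned with `traj$times`.
#' @export
trajectory_series <- function(traj, variable) {
  stopifnot(inherits(traj, "sd_trajectory"))
  if (!variable %in% names(traj$series))
    stop("unknown variable '", variable, "'; trajectory has: ",
         paste(names(traj$series), collapse = ", "), call. = FALSE)
  traj$series[[variable]]
}
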