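#' Parameters of the work-family conflict model
#'
#' All constants of the construction-employee work-family conflict model.
#' Satisfaction scales are dimensionless; times are in months. The defaults
#' are the model's study conditions:
#'
#' * `js0 = 5`, `fs0 = 1.5` — initial job and family satisfaction. Job
#'   satisfaction starts higher, reflecting a collectivist setting in which
#'   work life outranks family life.
#' * `je_start = 0.5`, `je_end = 0.7` — job experience grows linearly over
#'   the 36-month project.
#' * `workload_points` — the stepped workload schedule over the project
#'   stages: 6 through the decision and design stages, 9 then 12 through the
#'   first construction phase, dropping to 8 for the second phase.
#' * `work_flexibility = 1` — boundary-flexibility moderator (constant).
#' * `wifc_coeff = fiwc_coeff = 0.05` — conflict intensity coefficients.
#' * `org_support_gain = 0.1` — organizational support per unit job
#'   performance.
#' * `family_support_gain = 1` — family support per unit family involvement.
#' * `perf_divisor = 10`, `fam_involvement_scale = 100` — fixed scale factors
#'   in the performance and family-involvement equations.
#' * `working_time_gain = 1` — working time per unit workload (working time
#'   tracks the workload schedule).
#' * `js_decay_gain = 1`, `fs_decay_gain = 0.25` — erosion gains (per month)
#'   of the two satisfaction stocks per unit of the opposing conflict; see
#'   the package vignette for the calibration rationale.
#' * `delay_time_job = delay_time_family = 1` — relaxation times (months) of
#'   the first-order delays through which satisfaction acts on performance.
#'
#' @param js0,fs0 initial stock values.
#' @param je_start,je_end job-experience ramp endpoints (`je_end >= je_start`).
#' @param workload_points two-column matrix of workload breakpoints.
#' @param work_flexibility,wifc_coeff,fiwc_coeff,org_support_gain,family_support_gain
#'   moderator and coefficient values, all > 0.
#' @param perf_divisor,fam_involvement_scale,working_time_gain scale factors, > 0.
#' @param js_decay_gain,fs_decay_gain satisfaction erosion gains, > 0 (1/month).
#' @param delay_time_job,delay_time_family delay relaxation times (months), > 0.
#' @return an object of class `wfc_parameters` (a validated named list).
#' @export
wfc_parameters <- function(js0 = 5, fs0 = 1.5,
                           je_start = 0.5, je_end = 0.7,
                           workload_points = default_workload_points(),
                           work_flexibility = 1,
                           wifc_coeff = 0.05, fiwc_coeff = 0.05,
                           org_support_gain = 0.1, family_support_gain = 1,
                           perf_divisor = 10, fam_involvement_scale = 100,
                           working_time_gain = 1,
                           js_decay_gain = 1, fs_decay_gain = 0.25,
                           delay_time_job = 1, delay_time_family = 1) {
  p <- list(js0 = js0, fs0 = fs0, je_start = je_start, je_end = je_end,
            workload_points = as.matrix(workload_points),
            work_flexibility = work_flexibility,
            wifc_coeff = wifc_coeff, fiwc_coeff = fiwc_coeff,
            org_support_gain = org_support_gain,
            family_support_gain = family_support_gain,
            perf_divisor = perf_divisor,
            fam_involvement_scale = fam_involvement_scale,
            working_time_gain = working_time_gain,
            js_decay_gain = js_decay_gain, fs_decay_gain = fs_decay_gain,
            delay_time_job = delay_time_job,
            delay_time_family = delay_time_family)
  positive <- setdiff(names(p), c("workload_points", "je_start", "je_end",
                                  "js_decay_gain", "fs_decay_gain"))
  for (k in positive)
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || p[[k]] <= 0)
      stop("parameter '", k, "' must be a single positive number", call. = FALSE)
  # zero decay gains give the conflict-free variant with conserved stocks
  for (k in c("js_decay_gain", "fs_decay_gain"))
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || p[[k]] < 0)
      stop("parameter '", k, "' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(je_start) || !is.numeric(je_end) || je_end < je_start)
    stop("`je_end` must be >= `je_start`", call. = FALSE)
  table_function(p$workload_points)  # borrows the lookup-table validation
  structure(p, class = "wfc_parameters")
}

#' Default workload breakpoints
#'
#' The stepped workload schedule over the project life cycle, with duplicated
#' breakpoints at the stage transitions (months 4.5, 9 and 18) encoding the
#' steps: 6 in the decision and design stages, 9 then 12 in the first
#' construction phase, 8 in the second.
#'
#' @return two-column numeric matrix of `(x, y)` pairs.
#' @export
default_workload_points <- function() {
  cbind(x = c(0, 4.5, 4.5, 9, 9, 18, 18, 36),
        y = c(6, 6, 9, 9, 12, 12, 8, 8))
}

#' Project stage schedule
#'
#' The project life cycle covered by the model: decision (4.5 months), design
#' (4.5 months) and construction (27 months), the construction stage being
#' split into two phases at month 18 since project start. Employees are
#' assumed to stay with the project through all three stages.
#'
#' @param decision,design,construction stage durations, months.
#' @param construction_phase1_end end of the first construction phase,
#'   months since project start; must fall inside the construction stage.
#' @return an object of class `stage_schedule` with a `total` field.
#' @export
stage_schedule <- function(decision = 4.5, design = 4.5, construction = 27,
                           construction_phase1_end = 18) {
  stopifnot(decision > 0, design > 0, construction > 0,
            construction_phase1_end > 0)
  total <- decision + design + construction
  if (construction_phase1_end <= decision + design ||
      construction_phase1_end >= total)
    stop("`construction_phase1_end` must lie inside the construction stage",
         call. = FALSE)
  structure(list(decision = decision, design = design,
                 construction = construction,
                 construction_phase1_end = construction_phase1_end,
                 total = total),
            class = "stage_schedule")
}

#' Stage boundaries of a schedule
#'
#' @param schedule a [stage_schedule()].
#' @param merge_to_phase1 if `TRUE`, merge the decision and design stages and
#'   the first construction phase into a single interval, as used when
#'   classifying trends over the whole rising-workload period.
#' @return named numeric vector of interval boundaries (months).
#' @export
stage_breaks <- function(schedule, merge_to_phase1 = FALSE) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (merge_to_phase1)
    c(start = 0, phase1_end = schedule$construction_phase1_end,
      end = schedule$total)
  else
    c(start = 0, decision_end = schedule$decision,
      design_end = schedule$decision + schedule$design,
      phase1_end = schedule$construction_phase1_end,
      end = schedule$total)
}

#' Default lookup tables of the model
#'
#' The workload table is the stepped schedule in
#' `params$workload_points`; the job-experience table is the two-point linear
#' ramp from `(0, je_start)` to `(total, je_end)`. Display bounds mirror the
#' windows conventionally drawn for these tables and never affect evaluation.
#'
#' @param schedule a [stage_schedule()].
#' @param params a [wfc_parameters()].
#' @return list with `table_function` elements `workload` and
#'   `job_experience`.
#' @export
default_tables <- function(schedule = stage_schedule(),
                           params = wfc_parameters()) {
  stopifnot(inherits(schedule, "stage_schedule"),
            inherits(params, "wfc_parameters"))
  list(
    workload = table_function(params$workload_points,
                              display_bounds = list(c(0, 0), c(36, 16))),
    job_experience = table_function(
      cbind(x = c(0, schedule$total), y = c(params$je_start, params$je_end)),
      display_bounds = list(c(0, 0), c(36, 1))))
}

.guard_chain <- function(den, what, guard_epsilon) {
  if (abs(den) < guard_epsilon)
    .numerical_error(what, NA_real_,
                     sprintf("denominator %g below guard epsilon %g",
                             den, guard_epsilon))
  den
}

#' Work-domain auxiliary chain at one instant
#'
#' Evaluates the work-side algebra from the current states:
#' working time is proportional to workload; job involvement is
#' `job satisfaction x working time`; job performance is
#' `working time x job experience x job involvement x delayed job
#' satisfaction / perf_divisor`; organizational support responds to job
#' performance; job pressure is `workload / (job performance x organizational
#' support x work flexibility)`; and WIFC is
#' `wifc_coeff x job involvement x job pressure / work flexibility`.
#' Note WIFC scales as `1 / work_flexibility^2`: once directly and once
#' through job pressure.
#'
#' @param job_satisfaction,delayed_job_satisfaction current stock and delayed
#'   stock values.
#' @param workload,job_experience current lookup values.
#' @param params a [wfc_parameters()].
#' @param guard_epsilon denominators below this magnitude raise a numerical
#'   domain error.
#' @return named list with `working_time`, `job_involvement`,
#'   `job_performance`, `organizational_support`, `job_pressure`, `wifc`.
#' @export
work_chain <- function(job_satisfaction, delayed_job_satisfaction,
                       workload, job_experience,
                       params = wfc_parameters(), guard_epsilon = 1e-9) {
  stopifnot(inherits(params, "wfc_parameters"))
  working_time <- params$working_time_gain * workload
  job_involvement <- job_satisfaction * working_time
  job_performance <- working_time * job_experience * job_involvement *
    delayed_job_satisfaction / params$perf_divisor
  organizational_support <- params$org_support_gain * job_performance
  job_pressure <- workload /
    .guard_chain(job_performance * organizational_support *
                   params$work_flexibility, "job pressure", guard_epsilon)
  wifc <- params$wifc_coeff * job_involvement * job_pressure /
    params$work_flexibility
  list(working_time = working_time, job_involvement = job_involvement,
       job_performance = job_performance,
       organizational_support = organizational_support,
       job_pressure = job_pressure, wifc = wifc)
}

#' Family-domain auxiliary chain at one instant
#'
#' Family involvement is `fam_involvement_scale x family satisfaction /
#' working time` (long working hours crowd out the family role); family
#' support responds to family involvement; family performance is
#' `delayed family satisfaction x family involvement / perf_divisor`; family
#' pressure is `1 / (family support x family performance)`; and FIWC is
#' `fiwc_coeff x family involvement x family pressure`.
#'
#' @param family_satisfaction,delayed_family_satisfaction current stock and
#'   delayed stock values.
#' @param working_time current working time.
#' @param params a [wfc_parameters()].
#' @param guard_epsilon denominators below this magnitude raise a numerical
#'   domain error.
#' @return named list with `family_involvement`, `family_support`,
#'   `family_performance`, `family_pressure`, `fiwc`.
#' @export
family_chain <- function(family_satisfaction, delayed_family_satisfaction,
                         working_time,
                         params = wfc_parameters(), guard_epsilon = 1e-9) {
  stopifnot(inherits(params, "wfc_parameters"))
  family_involvement <- params$fam_involvement_scale * family_satisfaction /
    .guard_chain(working_time, "family involvement", guard_epsilon)
  family_support <- params$family_support_gain * family_involvement
  family_performance <- delayed_family_satisfaction * family_involvement /
    params$perf_divisor
  family_pressure <- 1 /
    .guard_chain(family_support * family_performance, "family pressure",
                 guard_epsilon)
  fiwc <- params$fiwc_coeff * family_involvement * family_pressure
  list(family_involvement = family_involvement,
       family_support = family_support,
       family_performance = family_performance,
       family_pressure = family_pressure, fiwc = fiwc)
}

#' Satisfaction rate equations
#'
#' Each conflict direction erodes the satisfaction stock of the opposing
#' domain: WIFC erodes family satisfaction and FIWC erodes job satisfaction,
#' linearly with configurable gains. With no conflict the stocks are
#' conserved.
#'
#' @param wifc,fiwc current conflict levels, >= 0.
#' @param params a [wfc_parameters()].
#' @return named list with `job_satisfaction_increment` and
#'   `family_satisfaction_increment` (per month, <= 0).
#' @export
satisfaction_increments <- function(wifc, fiwc, params = wfc_parameters()) {
  stopifnot(inherits(params, "wfc_parameters"))
  list(job_satisfaction_increment = -params$js_decay_gain * fiwc,
       family_satisfaction_increment = -params$fs_decay_gain * wifc)
}

#' Build the work-family conflict model
#'
#' Wires the 18 model variables — two stocks (job and family satisfaction),
#' two rates (their increments), thirteen auxiliaries and the work-flexibility
#' constant — plus the two first-order delay states through which
#' satisfaction acts on performance, into an [sd_model()] ready for
#' [run_model()].
#'
#' @param params a [wfc_parameters()].
#' @param schedule a [stage_schedule()].
#' @return an [sd_model()] with 20 variables (18 model variables + 2 delay
#'   states).
#' @export
build_wfc_model <- function(params = wfc_parameters(),
                            schedule = stage_schedule()) {
  stopifnot(inherits(params, "wfc_parameters"),
            inherits(schedule, "stage_schedule"))
  tabs <- default_tables(schedule, params)
  aux <- function(name, eq, env) sd_variable(name, "auxiliary",
                                             equation = do.call(substitute, list(eq, env)))
  p <- unclass(params)

  vars <- list(
    sd_variable("work_flexibility", "constant", value = params$work_flexibility),
    sd_variable("workload", "lookup", table = tabs$workload, input = "time"),
    sd_variable("job_experience", "lookup", table = tabs$job_experience,
                input = "time"),
    aux("working_time", quote(g * workload), list(g = p$working_time_gain)),
    aux("job_involvement", quote(job_satisfaction * working_time), list()),
    aux("job_performance",
        quote(working_time * job_experience * job_involvement *
                delayed_job_satisfaction / d),
        list(d = p$perf_divisor)),
    aux("organizational_support", quote(g * job_performance),
        list(g = p$org_support_gain)),
    aux("job_pressure",
        quote(qdiv(workload, job_performance * organizational_support *
                     work_flexibility)), list()),
    aux("wifc", quote(cf * job_involvement *
                        qdiv(job_pressure, work_flexibility)),
        list(cf = p$wifc_coeff)),
    aux("family_involvement",
        quote(s * qdiv(family_satisfaction, working_time)),
        list(s = p$fam_involvement_scale)),
    aux("family_support", quote(g * family_involvement),
        list(g = p$family_support_gain)),
    aux("family_performance",
        quote(delayed_family_satisfaction * family_involvement / d),
        list(d = p$perf_divisor)),
    aux("family_pressure",
        quote(qdiv(1, family_support * family_performance)), list()),
    aux("fiwc", quote(cf * family_involvement * family_pressure),
        list(cf = p$fiwc_coeff)),
    sd_variable("job_satisfaction_increment", "rate",
                equation = substitute(-(l) * fiwc, list(l = p$js_decay_gain))),
    sd_variable("family_satisfaction_increment", "rate",
                equation = substitute(-(l) * wifc, list(l = p$fs_decay_gain))),
    sd_variable("job_satisfaction", "stock", initial_value = params$js0,
                rates = "job_satisfaction_increment"),
    sd_variable("family_satisfaction", "stock", initial_value = params$fs0,
                rates = "family_satisfaction_increment"),
    sd_variable("delayed_job_satisfaction", "delay",
                input = "job_satisfaction",
                delay_time = params$delay_time_job,
                initial_value = params$js0),
    sd_variable("delayed_family_satisfaction", "delay",
                input = "family_satisfaction",
                delay_time = params$delay_time_family,
                initial_value = params$fs0))
  sd_model(vars, name = "work_family_conflict")
}

#' The four moderator scenarios
#'
#' * `current` — baseline, no overrides.
#' * `current_1` — work flexibility raised from 1 to 5.
#' * `current_2` — family-support gain raised from 1.0 to 2.0.
#' * `current_3` — organizational-support gain raised from 0.1 to 0.3.
#'
#' @param name one of `"current"`, `"current_1"`, `"current_2"`,
#'   `"current_3"`.
#' @return a [scenario_spec()].
#' @export
make_scenario <- function(name) {
  presets <- list(
    current   = list(),
    current_1 = list(work_flexibility = 5),
    current_2 = list(family_support_gain = 2),
    current_3 = list(org_support_gain = 0.3))
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(presets), collapse = ", "),
         call. = FALSE)
  scenario_spec(name, presets[[name]])
}

#' A named set of parameter overrides
#'
#' @param name scenario label.
#' @param overrides named list of [wfc_parameters()] values to replace;
#'   unknown names are a hard error.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.list(overrides))
  known <- names(formals(wfc_parameters))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown parameter(s) in scenario overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

#' Apply scenario overrides to a parameter set
#'
#' @param params a [wfc_parameters()].
#' @param scenario a [scenario_spec()] or scenario name.
#' @return a revalidated [wfc_parameters()].
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "wfc_parameters"))
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- unclass(params)
  for (k in names(scenario$overrides)) p[[k]] <- scenario$overrides[[k]]
  do.call(wfc_parameters, p)
}
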