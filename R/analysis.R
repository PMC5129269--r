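#' Run a moderator scenario
#'
#' Applies the scenario's parameter overrides, builds the model and runs it;
#' the trajectory is tagged with the scenario name.
#'
#' @param scenario a [scenario_spec()] or one of the scenario names accepted
#'   by [make_scenario()].
#' @param params baseline [wfc_parameters()].
#' @param schedule a [stage_schedule()].
#' @param config a [simulation_config()].
#' @return an `sd_trajectory`.
#' @export
run_scenario <- function(scenario = "current",
                         params = wfc_parameters(),
                         schedule = stage_schedule(),
                         config = simulation_config()) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- apply_scenario(params, scenario)
  run_model(build_wfc_model(p, schedule), config,
            scenario_name = scenario$name)
}

#' Classify per-stage trends of one series
#'
#' For each stage interval the series is classified as `rising`, `falling`
#' or `flat` by the sign of `last - first` within the interval; differences
#' no larger than `tolerance` count as flat. Interval boundaries default to
#' the four project stages; pass `breaks` (e.g.
#' `stage_breaks(schedule, merge_to_phase1 = TRUE)`) to merge stages.
#'
#' Stages are right-open (`[lo, hi)`, the last one closed): a saved point on
#' a stage boundary belongs to the *following* stage, mirroring the
#' right-continuity of the stepped workload schedule — at month 18 the
#' workload has already dropped, so that point opens the second construction
#' phase rather than closing the first.
#'
#' @param traj an `sd_trajectory`.
#' @param variable series to classify.
#' @param schedule a [stage_schedule()] supplying the default boundaries.
#' @param tolerance flat threshold on `|last - first|`.
#' @param breaks optional numeric vector of interval boundaries (months)
#'   overriding the schedule's.
#' @return an object of class `trend_report`: `variable`, `tolerance` and a
#'   `stages` data frame with `start`, `end`, `first`, `last` and `trend`.
#' @export
trend_signs <- function(traj, variable, schedule = stage_schedule(),
                        tolerance = 1e-6, breaks = NULL) {
  stopifnot(inherits(traj, "sd_trajectory"))
  y <- trajectory_series(traj, variable)
  if (is.null(breaks)) breaks <- stage_breaks(schedule)
  breaks <- sort(unique(as.numeric(breaks)))
  if (length(breaks) < 2L) stop("need at least two stage boundaries", call. = FALSE)
  t <- traj$times
  rows <- lapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    last_stage <- i == length(breaks) - 1L
    sel <- which(t >= lo - 1e-12 &
                   (if (last_stage) t <= hi + 1e-12 else t < hi - 1e-12))
    if (length(sel) < 2L)
      stop("stage [", lo, ", ", hi, "] contains fewer than two saved points",
           call. = FALSE)
    first <- y[sel[1L]]; last <- y[sel[length(sel)]]
    d <- last - first
    data.frame(start = lo, end = hi, first = first, last = last,
               trend = if (abs(d) <= tolerance) "flat"
                       else if (d > 0) "rising" else "falling",
               stringsAsFactors = FALSE)
  })
  structure(list(variable = variable, tolerance = tolerance,
                 stages = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report> '", x$variable, "' (flat tolerance ", x$tolerance,
      ")\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' Compare two scenario trajectories
#'
#' Per variable: final values, time-averaged values, the relative change of
#' the alternative against the baseline at the final time
#' (`(alt - base) / |base|`), and a dominance flag (`TRUE` when the
#' alternative is at least the baseline at every saved point after the
#' start).
#'
#' @param base,alt trajectories on identical time grids.
#' @param variables variables to compare; defaults to the four outcome
#'   variables (job/family satisfaction and performance).
#' @return an object of class `comparison_report`: `base`, `alt` and a
#'   `table` data frame.
#' @export
compare_runs <- function(base, alt,
                         variables = c("job_satisfaction",
                                       "family_satisfaction",
                                       "job_performance",
                                       "family_performance")) {
  stopifnot(inherits(base, "sd_trajectory"), inherits(alt, "sd_trajectory"))
  if (length(base$times) != length(alt$times) ||
      any(abs(base$times - alt$times) > 1e-9))
    stop("trajectories are on different time grids and cannot be compared",
         call. = FALSE)
  after0 <- base$times > base$times[1L]
  rows <- lapply(variables, function(v) {
    b <- trajectory_series(base, v); a <- trajectory_series(alt, v)
    n <- length(b)
    data.frame(variable = v,
               final_base = b[n], final_alt = a[n],
               mean_base = mean(b), mean_alt = mean(a),
               rel_change = (a[n] - b[n]) / abs(b[n]),
               dominates = all(a[after0] >= b[after0]),
               stringsAsFactors = FALSE)
  })
  structure(list(base = base$scenario_name, alt = alt$scenario_name,
                 table = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> '", x$alt, "' vs baseline '", x$base, "'\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' Summarize a work-family conflict run
#'
#' @param traj an `sd_trajectory` containing `wifc` and `fiwc` series.
#' @return an object of class `run_summary`: the fraction of saved points
#'   with WIFC > FIWC, final values of the two stocks and the four outcome
#'   variables, and the range of each conflict series.
#' @export
run_summary <- function(traj) {
  stopifnot(inherits(traj, "sd_trajectory"))
  wifc <- trajectory_series(traj, "wifc")
  fiwc <- trajectory_series(traj, "fiwc")
  n <- length(traj$times)
  finals <- vapply(c("job_satisfaction", "family_satisfaction",
                     "job_performance", "family_performance"),
                   function(v) trajectory_series(traj, v)[n], numeric(1))
  structure(list(scenario_name = traj$scenario_name,
                 frac_wifc_gt_fiwc = mean(wifc > fiwc),
                 final = as.list(finals),
                 wifc_range = range(wifc),
                 fiwc_range = range(fiwc)),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> scenario '", x$scenario_name, "'\n",
      "  WIFC > FIWC at ", sprintf("%.1f%%", 100 * x$frac_wifc_gt_fiwc),
      " of saved points\n",
      "  WIFC in [", sprintf("%.6g", x$wifc_range[1]), ", ",
      sprintf("%.6g", x$wifc_range[2]), "], FIWC in [",
      sprintf("%.6g", x$fiwc_range[1]), ", ",
      sprintf("%.6g", x$fiwc_range[2]), "]\n", sep = "")
  cat("  final:", paste(sprintf("%s = %.6g", names(x$final),
                                unlist(x$final)), collapse = ", "), "\n")
  invisible(x)
}
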