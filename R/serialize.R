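#' Write a model to JSON
#'
#' Serializes every variable with its role, dependencies and role-specific
#' payload. Equations are stored as deparsed R expressions (17 significant
#' digits, so numeric literals survive the round trip); [read_model_json()]
#' restores them with `parse()`. The write/read round trip is lossless.
#'
#' @param model an [sd_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sd_model"))
  vars <- lapply(unname(model$variables), function(v) {
    rec <- list(name = v$name, role = v$role,
                dependencies = as.list(v$dependencies))
    if (!is.null(v$equation))
      rec$equation <- paste(deparse(v$equation, control = "digits17"),
                            collapse = " ")
    if (!is.null(v$initial_value)) rec$initial_value <- v$initial_value
    if (!is.null(v$rates)) rec$rates <- as.list(v$rates)
    if (!is.null(v$delay_time)) rec$delay_time <- v$delay_time
    if (!is.null(v$input)) rec$input <- v$input
    if (!is.null(v$value)) rec$value <- v$value
    if (!is.null(v$table)) {
      rec$table <- list(points = unname(apply(v$table$points, 1L, as.list,
                                              simplify = FALSE)))
      if (!is.null(v$table$display_bounds))
        rec$table$display_bounds <- v$table$display_bounds
    }
    rec
  })
  jsonlite::write_json(list(name = model$name, variables = vars), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return an [sd_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  vars <- lapply(doc$variables, function(rec) {
    table <- NULL
    if (!is.null(rec$table)) {
      pts <- do.call(rbind, lapply(rec$table$points, function(p)
        c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
      db <- rec$table$display_bounds
      if (!is.null(db)) db <- lapply(db, function(p) as.numeric(unlist(p)))
      table <- table_function(pts, display_bounds = db)
    }
    sd_variable(
      name = rec$name, role = rec$role,
      equation = rec$equation,
      dependencies = as.character(unlist(rec$dependencies)),
      initial_value = rec$initial_value,
      rates = if (!is.null(rec$rates)) as.character(unlist(rec$rates)),
      delay_time = rec$delay_time, input = rec$input,
      value = rec$value, table = table)
  })
  sd_model(vars, name = doc$name)
}

#' Write a trajectory to CSV
#'
#' First column `time` (months), then one column per model variable in
#' alphabetical order; values carry 12 significant digits.
#'
#' @param traj an [run_model()] trajectory.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sd_trajectory"))
  df <- cbind(data.frame(time = traj$times),
              traj$series[, sort(names(traj$series)), drop = FALSE])
  fmt <- as.data.frame(lapply(df, function(col) sprintf("%.12g", col)))
  names(fmt) <- names(df)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path a file written by [write_trajectory_csv()].
#' @return list with `times` and `series` (data frame); note that the
#'   configuration and scenario tag are not stored in the CSV.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time")
    stop("not a trajectory CSV (first column must be 'time'): ", path,
         call. = FALSE)
  list(times = df$time, series = df[, -1L, drop = FALSE])
}

#' Write an analysis report to JSON
#'
#' Trend, comparison and run-summary reports serialize losslessly
#' (`digits = NA`); the class tag is stored so [read_report_json()] restores
#' an equal object.
#'
#' @param report a `trend_report`, `comparison_report` or `run_summary`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cls <- intersect(class(report),
                   c("trend_report", "comparison_report", "run_summary"))
  if (!length(cls)) stop("not a serializable report object", call. = FALSE)
  payload <- list(report_class = cls[1L], content = unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report from JSON
#'
#' @param path a file written by [write_report_json()].
#' @return the restored report object.
#' @export
read_report_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  content <- doc$content
  if (doc$report_class == "trend_report")
    content$stages <- as.data.frame(content$stages)
  if (doc$report_class == "comparison_report")
    content$table <- as.data.frame(content$table)
  structure(content, class = doc$report_class)
}
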