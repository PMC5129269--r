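#' Declare a model variable
#'
#' A stock-and-flow model is a named collection of variables, each with one of
#' six roles:
#'
#' * `"stock"` — a state variable advanced by integrating its rate
#'   variable(s); requires `initial_value` and `rates`.
#' * `"rate"` — the time-derivative feeding a stock; an algebraic `equation`.
#' * `"auxiliary"` — an instantaneous algebraic variable; an `equation`.
#' * `"constant"` — a fixed number (`value`); no dependencies.
#' * `"lookup"` — a [table_function()] driven by `input` (another variable or
#'   the literal `"time"`).
#' * `"delay"` — a first-order exponential delay of exactly one `input`
#'   variable with relaxation time `delay_time` (months) and an explicit
#'   `initial_value`; an additional integrated state.
#'
#' Equations are unevaluated R expressions over the names of the variable's
#' dependencies plus `time`. Divisions that may approach zero should be
#' written with `qdiv(numerator, denominator)`, which the engine guards
#' against denominators smaller in magnitude than the configured epsilon.
#' Dependencies default to the variables named in the expression.
#'
#' @param name variable identifier (must be a syntactic R name).
#' @param role one of `"stock"`, `"rate"`, `"auxiliary"`, `"constant"`,
#'   `"lookup"`, `"delay"`.
#' @param equation an unevaluated expression (`quote(...)`) or a string to be
#'   parsed, for `rate`/`auxiliary` roles.
#' @param dependencies character vector of variable names the equation reads;
#'   defaults to the names appearing in `equation`.
#' @param initial_value starting value (required for `stock` and `delay`).
#' @param rates for `stock`: the rate variable(s) integrated into it.
#' @param delay_time for `delay`: relaxation time in months, > 0.
#' @param input for `delay`/`lookup`: the single driving variable name
#'   (`"time"` allowed for lookups).
#' @param value for `constant`: the number.
#' @param table for `lookup`: a [table_function()].
#' @return an object of class `sd_variable`.
#' @export
sd_variable <- function(name, role,
                        equation = NULL, dependencies = NULL,
                        initial_value = NULL, rates = NULL,
                        delay_time = NULL, input = NULL,
                        value = NULL, table = NULL) {
  roles <- c("stock", "rate", "auxiliary", "constant", "lookup", "delay")
  if (!is.character(name) || length(name) != 1L || name != make.names(name))
    stop("`name` must be a single syntactic identifier", call. = FALSE)
  role <- match.arg(role, roles)
  if (is.character(equation))
    equation <- parse(text = equation, keep.source = FALSE)[[1L]]

  switch(role,
    stock = {
      if (is.null(initial_value) || !is.finite(initial_value))
        stop("stock '", name, "' needs a finite `initial_value`", call. = FALSE)
      if (is.null(rates) || !is.character(rates) || length(rates) < 1L)
        stop("stock '", name, "' must list the rate variable(s) integrating into it",
             call. = FALSE)
      dependencies <- rates
    },
    delay = {
      if (is.null(initial_value) || !is.finite(initial_value))
        stop("delay '", name, "' needs a finite `initial_value`", call. = FALSE)
      if (is.null(delay_time) || !is.numeric(delay_time) || delay_time <= 0)
        stop("delay '", name, "' needs `delay_time` > 0", call. = FALSE)
      if (is.null(input) || length(input) != 1L)
        stop("delay '", name, "' needs exactly one `input` variable", call. = FALSE)
      dependencies <- input
    },
    constant = {
      if (is.null(value) || !is.finite(value))
        stop("constant '", name, "' needs a finite `value`", call. = FALSE)
      if (!is.null(dependencies) && length(dependencies))
        stop("constant '", name, "' cannot have dependencies", call. = FALSE)
      dependencies <- character(0)
    },
    lookup = {
      if (!inherits(table, "table_function"))
        stop("lookup '", name, "' needs a `table_function`", call. = FALSE)
      if (is.null(input) || length(input) != 1L)
        stop("lookup '", name, "' needs a single `input` (a variable or \"time\")",
             call. = FALSE)
      dependencies <- setdiff(input, "time")
    },
    {
      # rate / auxiliary
      if (is.null(equation) || !(is.call(equation) || is.name(equation) ||
                                 is.numeric(equation)))
        stop(role, " '", name, "' needs an `equation` expression", call. = FALSE)
      if (is.null(dependencies))
        dependencies <- setdiff(all.vars(equation), c("time", "qdiv"))
    }
  )

  structure(
    list(name = name, role = role, equation = equation,
         dependencies = as.character(dependencies),
         initial_value = initial_value, rates = rates,
         delay_time = delay_time, input = input,
         value = value, table = table),
    class = "sd_variable")
}

#' Assemble a stock-and-flow model
#'
#' Validates that every declared dependency names an existing variable and
#' that the instantaneous dependency subgraph (the equations evaluated within
#' a time step; stocks, delays and constants act as sources) is acyclic.
#'
#' @param variables list of [sd_variable()] objects.
#' @param name model name.
#' @return an object of class `sd_model`.
#' @export
sd_model <- function(variables, name = "model") {
  if (inherits(variables, "sd_variable")) variables <- list(variables)
  stopifnot(all(vapply(variables, inherits, logical(1), "sd_variable")))
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicated variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(variables) <- nms
  for (v in variables) {
    missing <- setdiff(v$dependencies, nms)
    if (length(missing))
      stop("variable '", v$name, "' depends on undeclared variable(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (v$role == "stock") {
      bad <- nms[match(v$rates, nms)][
        vapply(variables[v$rates], `[[`, character(1), "role") != "rate"]
      if (length(bad))
        stop("stock '", v$name, "' integrates non-rate variable(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  model <- structure(list(variables = variables, name = name),
                     class = "sd_model")
  # surfaces an informative error if the instantaneous subgraph has a cycle
  instantaneous_order(build_dependency_graph(model))
  model
}

#' @export
print.sd_model <- function(x, ...) {
  roles <- vapply(x$variables, `[[`, character(1), "role")
  cat("<sd_model> '", x$name, "': ", length(roles), " variables (",
      paste(sprintf("%d %s", as.integer(table(roles)), names(table(roles))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Variable roles of a model
#'
#' @param model an [sd_model()].
#' @return named character vector mapping variable name to role.
#' @export
variable_roles <- function(model) {
  stopifnot(inherits(model, "sd_model"))
  vapply(model$variables, `[[`, character(1), "role")
}
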