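#' Piecewise-linear lookup table
#'
#' A table function maps a driving quantity (usually simulation time, in
#' months) to a dimensionless value by linear interpolation between ordered
#' breakpoints. A breakpoint `x` may appear exactly twice with different `y`
#' values, encoding a step discontinuity; evaluation is right-continuous at
#' such a step, i.e. at the duplicated `x` the later `y` applies. Outside the
#' breakpoint range the nearest endpoint `y` is returned, so the function is
#' total over the reals.
#'
#' @param points two-column numeric matrix or data frame of `(x, y)`
#'   breakpoints with non-decreasing `x`; at least two rows; no `x` value may
#'   occur more than twice.
#' @param display_bounds optional list of two `(x, y)` pairs giving the
#'   plotting window some authoring tools attach to a lookup. Metadata only;
#'   never used in evaluation.
#' @return an object of class `table_function`.
#' @examples
#' ramp <- table_function(cbind(c(0, 36), c(0.5, 0.7)))
#' evaluate_lookup(ramp, 18)
#' @export
table_function <- function(points, display_bounds = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a two-column numeric matrix of (x, y) pairs", call. = FALSE)
  if (nrow(points) < 2L)
    stop("a table function needs at least 2 points", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("table function points must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  x <- points[, "x"]
  if (is.unsorted(x))
    stop("table function x values must be non-decreasing", call. = FALSE)
  if (any(table(x) > 2L))
    stop("an x value may appear at most twice (a step discontinuity)", call. = FALSE)
  if (!is.null(display_bounds)) {
    display_bounds <- lapply(display_bounds, as.numeric)
    if (length(display_bounds) != 2L || any(lengths(display_bounds) != 2L))
      stop("`display_bounds` must be two (x, y) pairs", call. = FALSE)
  }
  structure(list(points = points, display_bounds = display_bounds),
            class = "table_function")
}

#' Evaluate a lookup table
#'
#' Linear interpolation between the bracketing breakpoints; right-continuous
#' at duplicated breakpoints (the later `y` applies at the shared `x`);
#' clamped to the nearest endpoint outside the breakpoint range.
#'
#' @param table a [table_function()].
#' @param x numeric vector of evaluation points (months for the time-driven
#'   tables of the work-family conflict model).
#' @return numeric vector of the same length as `x`.
#' @export
evaluate_lookup <- function(table, x) {
  stopifnot(inherits(table, "table_function"))
  px <- table$points[, "x"]
  py <- table$points[, "y"]
  n <- length(px)
  vapply(as.numeric(x), function(xi) {
    i <- findInterval(xi, px)          # largest i with px[i] <= xi
    if (i == 0L) return(py[1L])        # below range: clamp to first point
    if (i >= n) return(py[n])
    if (px[i] == xi) return(py[i])     # duplicated x resolves to the later y
    py[i] + (py[i + 1L] - py[i]) * (xi - px[i]) / (px[i + 1L] - px[i])
  }, numeric(1))
}

#' @export
print.table_function <- function(x, ...) {
  cat("<table_function> ", nrow(x$points), " points on x in [",
      x$points[1L, "x"], ", ", x$points[nrow(x$points), "x"], "]\n", sep = "")
  print(x$points)
  invisible(x)
}
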