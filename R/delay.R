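#' Advance a first-order exponential delay by one Euler step
#'
#' A first-order delay with relaxation time `D` obeys
#' `dy/dt = (x - y) / D`, so a constant input is approached exponentially:
#' `y(t) = x + (y0 - x) exp(-t / D)`. The engine advances each delay state
#' with the same explicit Euler step used for stocks:
#' `y <- y + dt * (x - y) / D`.
#'
#' @param current_output current delay state `y`.
#' @param input current value of the delayed variable `x`.
#' @param delay_time relaxation time `D` in months, > 0.
#' @param dt integration step in months, > 0.
#' @return the delay state after one step.
#' @examples
#' delay1_update(1, 0, 1, 0.5)  # 0.5
#' @export
delay1_update <- function(current_output, input, delay_time, dt) {
  if (!is.numeric(delay_time) || length(delay_time) != 1L || delay_time <= 0)
    stop("`delay_time` must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  current_output + dt * (input - current_output) / delay_time
}
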