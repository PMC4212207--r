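#' Voltage-clamp step/tail protocol
#'
#' A sweep family protocol: hold, step to each test voltage in turn, then
#' return to a tail voltage at which the inward tail current is measured.
#' Forward protocols step from a negative holding voltage to increasingly
#' positive voltages; reverse protocols (used to interrogate inside-out
#' channels from a positive holding voltage) step increasingly negative.
#'
#' @param holding_voltage mV, held before each step (channels assumed
#'   equilibrated here).
#' @param step_voltages Strictly monotone vector of test voltages, mV
#'   (increasing = forward protocol, decreasing = reverse).
#' @param holding_duration,step_duration,tail_duration Epoch durations, ms.
#' @param tail_voltage mV; defaults to the holding voltage, as in the standard
#'   protocol.
#' @param sample_interval ms; must resolve the step epoch (<= step_duration/10).
#' @return A \code{voltage_protocol} object.
#' @export
#' @examples
#' # the standard forward family: -110 to +80 mV in 10 mV increments
#' voltage_protocol(-110, seq(-110, 80, by = 10))
voltage_protocol <- function(holding_voltage, step_voltages,
                             holding_duration = 50, step_duration = 100,
                             tail_voltage = holding_voltage,
                             tail_duration = 50, sample_interval = 0.5) {
  stopifnot(is.numeric(holding_voltage), length(holding_voltage) == 1,
            is.numeric(step_voltages), length(step_voltages) >= 1,
            is.numeric(tail_voltage), length(tail_voltage) == 1)
  d <- diff(step_voltages)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("step_voltages must be strictly increasing (forward) or strictly ",
         "decreasing (reverse)")
  for (dur in c(holding = holding_duration, step = step_duration,
                tail = tail_duration)) {
    if (!is.numeric(dur) || length(dur) != 1 || dur <= 0)
      stop("all protocol durations must be positive")
  }
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (sample_interval > step_duration / 10)
    stop("sample_interval must be <= step_duration / 10")
  structure(list(holding_voltage = holding_voltage,
                 step_voltages = as.numeric(step_voltages),
                 holding_duration = holding_duration,
                 step_duration = step_duration,
                 tail_voltage = tail_voltage,
                 tail_duration = tail_duration,
                 sample_interval = sample_interval),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  dir <- if (length(x$step_voltages) < 2 ||
             diff(x$step_voltages)[1] > 0) "forward" else "reverse"
  cat(sprintf(
    "<voltage protocol> %s: hold %g mV (%g ms) -> steps %g..%g mV (n=%d, %g ms) -> tail %g mV (%g ms), dt %g ms\n",
    dir, x$holding_voltage, x$holding_duration,
    x$step_voltages[1], x$step_voltages[length(x$step_voltages)],
    length(x$step_voltages), x$step_duration,
    x$tail_voltage, x$tail_duration, x$sample_interval))
  invisible(x)
}

# Sample counts per epoch and the full time base (t = 0 at sweep start,
# spacing = sample_interval). The first sample of each epoch falls one
# sample_interval after the voltage switch.
.protocol_epochs <- function(protocol) {
  dt <- protocol$sample_interval
  n_hold <- max(1L, as.integer(round(protocol$holding_duration / dt)))
  n_step <- max(1L, as.integer(round(protocol$step_duration / dt)))
  n_tail <- max(1L, as.integer(round(protocol$tail_duration / dt)))
  n <- n_hold + n_step + n_tail
  list(dt = dt, n_hold = n_hold, n_step = n_step, n_tail = n_tail, n = n,
       time = (seq_len(n) - 1L) * dt,
       epoch = rep(c("holding", "step", "tail"),
                   times = c(n_hold, n_step, n_tail)))
}
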