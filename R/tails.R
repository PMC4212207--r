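#' Tail-current measurement window
#'
#' How the tail amplitude is read off after the return to the tail voltage.
#' \code{mean}: average current over [delay, delay + width] after the tail
#' step (default 2-5 ms: late enough to skip capacitive settling, early
#' enough to precede most deactivation decay at typical kinetics).
#' \code{peak}: largest baseline-subtracted excursion after \code{delay}.
#' \code{exponential_extrapolation}: fit a single exponential to the decay
#' after \code{delay} and back-extrapolate to the instant of the voltage step.
#'
#' @param mode One of \code{"mean"}, \code{"peak"},
#'   \code{"exponential_extrapolation"}.
#' @param delay_after_step ms (>= 0).
#' @param width ms (> 0; used by mean mode and as the fit span otherwise).
#' @return A \code{tail_window} object.
#' @export
tail_window <- function(mode = c("mean", "peak", "exponential_extrapolation"),
                        delay_after_step = 2, width = 3) {
  mode <- match.arg(mode)
  if (delay_after_step < 0) stop("delay_after_step must be >= 0")
  if (width <= 0) stop("width must be > 0")
  structure(list(mode = mode, delay_after_step = delay_after_step,
                 width = width),
            class = "tail_window")
}

#' Activation curve
#'
#' Normalized tail-current amplitudes as a function of the preceding
#' depolarization voltage. Values are nonnegative fractions of maximal
#' activation, with maximum 1 after normalization.
#'
#' @param step_voltages Depolarization voltages, mV.
#' @param normalized_tail Normalized amplitudes in [0, 1] up to noise (small
#'   excursions outside are tolerated); \code{\link{extract_tails}} normalizes
#'   so the maximum is exactly 1, while model-generated curves may top out
#'   slightly below 1.
#' @param sem Optional per-voltage SEM.
#' @param n_bilayers Optional replicate count.
#' @return An \code{activation_curve} object (data.frame-backed).
#' @export
activation_curve <- function(step_voltages, normalized_tail, sem = NULL,
                             n_bilayers = NULL) {
  if (length(step_voltages) != length(normalized_tail))
    stop("step_voltages and normalized_tail must have equal length")
  if (!is.null(sem) && length(sem) != length(step_voltages))
    stop("sem must match step_voltages in length")
  # noisy normalized tails may stray slightly outside [0, 1]; anything far
  # outside signals unnormalized input
  if (any(normalized_tail < -0.2) || max(normalized_tail) > 1.2)
    stop("normalized_tail must lie in [0, 1] up to noise (normalize first)")
  df <- data.frame(step_voltage = as.numeric(step_voltages),
                   normalized_tail = as.numeric(normalized_tail))
  if (!is.null(sem)) df$sem <- as.numeric(sem)
  structure(df, class = c("activation_curve", "data.frame"),
            n_bilayers = n_bilayers)
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("<activation curve> %d voltages, %g to %g mV\n",
              nrow(x), min(x$step_voltage), max(x$step_voltage)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# single-exponential back-extrapolation of a tail decay to te = 0
.tail_extrapolate <- function(te, i_sub) {
  a0 <- i_sub[1]
  if (a0 == 0) return(0)
  tau0 <- max(diff(range(te)), 1e-3)
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, tau = tau0),
    fn = function(p) i_sub - p[["a"]] * exp(-(te - te[1]) / p[["tau"]]),
    lower = c(-Inf, 1e-6))
  p <- stats::coef(fit)
  p[["a"]] * exp(te[1] / p[["tau"]])
}

#' Extract a normalized tail-current activation curve from a sweep family
#'
#' Per sweep: the baseline (mean current over the final 20% of the holding
#' epoch) is subtracted, the tail amplitude is measured according to the
#' window mode, and amplitudes are normalized by the largest absolute
#' amplitude in the family. Reported values are nonnegative fractions of
#' maximal activation regardless of the (inward, negative) sign of the raw
#' tail currents.
#'
#' @param family A \code{\link{current_family}} with a known protocol.
#' @param window A \code{\link{tail_window}}.
#' @return An \code{\link{activation_curve}}.
#' @export
extract_tails <- function(family, window = tail_window()) {
  stopifnot(inherits(family, "current_family"))
  if (is.null(family$protocol))
    stop("family has no protocol; tail epoch unknown")
  stopifnot(inherits(window, "tail_window"))
  protocol <- family$protocol
  ep <- .protocol_epochs(protocol)
  if (window$mode == "mean" &&
      window$delay_after_step + window$width > protocol$tail_duration + 1e-9)
    stop("tail window [", window$delay_after_step, ", ",
         window$delay_after_step + window$width,
         "] ms exceeds the tail epoch (", protocol$tail_duration, " ms)")
  if (window$delay_after_step > protocol$tail_duration)
    stop("tail window delay exceeds the tail epoch")

  base_idx <- seq.int(from = ep$n_hold - max(1L, floor(ep$n_hold * 0.2)) + 1L,
                      to = ep$n_hold)
  tail_idx <- ep$n_hold + ep$n_step + seq_len(ep$n_tail)
  te <- seq_len(ep$n_tail) * ep$dt # elapsed time since the tail step

  amps <- apply(family$traces, 1L, function(trace) {
    baseline <- mean(trace[base_idx])
    i_tail <- trace[tail_idx] - baseline
    switch(window$mode,
      mean = {
        sel <- te >= window$delay_after_step &
               te <= window$delay_after_step + window$width
        mean(i_tail[sel])
      },
      peak = {
        sel <- te >= window$delay_after_step
        i_sel <- i_tail[sel]
        i_sel[which.max(abs(i_sel))]
      },
      exponential_extrapolation = {
        sel <- te >= window$delay_after_step
        .tail_extrapolate(te[sel], i_tail[sel])
      })
  })
  max_amp <- max(abs(amps))
  if (max_amp <= .Machine$double.eps * 1e3)
    stop("all tail amplitudes are zero; cannot normalize activation curve")
  activation_curve(protocol$step_voltages, abs(amps) / max_amp)
}
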