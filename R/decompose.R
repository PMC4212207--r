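#' Decompose an observed V_mid shift into surface-charge and specific parts
#'
#' The surface-charge component is the offset predicted by leaflet
#' electrostatics for the composition change (\code{\link{surface_offset}} of
#' the test bilayer minus that of the reference bilayer); the lipid-specific
#' component is defined as the residual, so the two add back to the observed
#' shift exactly.
#'
#' @param observed_shift Measured \eqn{\Delta V_{mid}}, mV.
#' @param bilayer \code{\link{bilayer_spec}} of the test condition.
#' @param reference Optional \code{\link{bilayer_spec}} of the reference
#'   condition; default NULL means a symmetric (zero-offset) reference.
#' @param registry Lipid species table.
#' @param condition Label carried through to outputs.
#' @return A \code{shift_decomposition} object with fields
#'   \code{observed_shift}, \code{surface_component}, \code{specific_component}
#'   (mV) and \code{condition}.
#' @export
#' @examples
#' b <- bilayer_spec(inner = c(DPhPC = 0.91, POPA = 0.09), outer = c(DPhPC = 1))
#' decompose_shift(50, b) # surface ~ +20 mV, specific ~ +30 mV
decompose_shift <- function(observed_shift, bilayer, reference = NULL,
                            registry = default_lipid_registry(),
                            condition = "") {
  stopifnot(is.numeric(observed_shift), length(observed_shift) == 1)
  surface <- surface_offset(bilayer, registry)$predicted_offset
  if (!is.null(reference))
    surface <- surface - surface_offset(reference, registry)$predicted_offset
  structure(list(observed_shift = observed_shift,
                 surface_component = surface,
                 specific_component = observed_shift - surface,
                 condition = condition),
            class = "shift_decomposition")
}

#' @export
print.shift_decomposition <- function(x, ...) {
  cat(sprintf("<shift decomposition>%s\n",
              if (nzchar(x$condition)) paste0(" ", x$condition) else ""))
  cat(sprintf("  observed %+.1f mV = surface charge %+.1f mV + lipid-specific %+.1f mV\n",
              x$observed_shift, x$surface_component, x$specific_component))
  invisible(x)
}

#' Lipid-specific shift from symmetric-membrane comparisons
#'
#' When both leaflets of both conditions have the same composition, surface
#' charge effects on the sensor cancel, so the whole V_mid difference is
#' attributed to the lipid-specific mechanism.
#'
#' @param v_mid_mixture,v_mid_reference Fitted midpoints, mV, both from
#'   leaflet-symmetric membranes.
#' @return The specific shift \code{v_mid_mixture - v_mid_reference}, mV.
#' @export
#' @examples
#' specific_shift_symmetric(-40, -71) # +31 mV PA-specific component
specific_shift_symmetric <- function(v_mid_mixture, v_mid_reference) {
  v_mid_mixture - v_mid_reference
}

#' Fit the saturating mole-fraction dose-response of V_mid
#'
#' Least-squares fit of
#' \deqn{V_{mid}(x) = V_{baseline} + \Delta V_{max} \frac{x^h}{x^h + K_{1/2}^h}}
#' to a titration of activation midpoints against lipid mole fraction. The
#' default is the one-site rectangular hyperbola (\eqn{h = 1}); set
#' \code{hill = TRUE} to also fit the exponent.
#'
#' @param mole_fractions Lipid mole fractions (at least 3 distinct values,
#'   ideally including the x = 0 baseline).
#' @param v_mids Fitted midpoints at each mole fraction, mV.
#' @param hill Fit a Hill exponent as a third shape parameter.
#' @return A \code{dose_response_fit} with \code{baseline_v_mid},
#'   \code{delta_v_max}, \code{k_half}, optional \code{hill}, \code{rss},
#'   \code{degenerate} flag.
#' @export
#' @examples
#' x <- c(0, 0.05, 0.1, 0.25, 0.5, 1)
#' v <- c(-71, -60, -43, -40, -33, -31)
#' fit_saturation(x, v)
fit_saturation <- function(mole_fractions, v_mids, hill = FALSE) {
  x <- as.numeric(mole_fractions)
  y <- as.numeric(v_mids)
  if (length(x) != length(y)) stop("mole_fractions and v_mids lengths differ")
  if (any(x < 0)) stop("mole fractions must be >= 0")
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct mole fractions")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  degenerate <- diff(range(y)) < 1e-8
  base0 <- y[1]
  dmax0 <- y[length(y)] - base0
  k0 <- {
    half <- base0 + dmax0 / 2
    xs <- x[x > 0]
    if (abs(dmax0) > 0) {
      cross <- .half_crossing(x, y, half)
      max(cross, min(xs) / 2)
    } else stats::median(xs)
  }
  if (degenerate) {
    return(structure(list(baseline_v_mid = mean(y), delta_v_max = 0,
                          k_half = k0, hill = if (hill) 1 else NULL,
                          rss = sum((y - mean(y))^2), degenerate = TRUE),
                     class = "dose_response_fit"))
  }
  par <- c(baseline = base0, dmax = dmax0, k = k0)
  lower <- c(-Inf, -Inf, 1e-9)
  upper <- c(Inf, Inf, Inf)
  if (hill) { par <- c(par, h = 1); lower <- c(lower, 0.1); upper <- c(upper, 10) }
  model <- function(p) {
    h <- if (hill) p[["h"]] else 1
    p[["baseline"]] + p[["dmax"]] * x^h / (x^h + p[["k"]]^h)
  }
  fit <- minpack.lm::nls.lm(
    par = par, fn = function(p) y - model(p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-13,
                                         maxiter = 1000))
  p <- stats::coef(fit)
  structure(list(baseline_v_mid = p[["baseline"]], delta_v_max = p[["dmax"]],
                 k_half = p[["k"]], hill = if (hill) p[["h"]] else NULL,
                 rss = sum((y - model(p))^2), degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose-response fit> baseline %.1f mV, dVmax %+.1f mV, K1/2 %.3g%s (rss %.3g)%s\n",
    x$baseline_v_mid, x$delta_v_max, x$k_half,
    if (!is.null(x$hill)) sprintf(", Hill %.2f", x$hill) else "",
    x$rss, if (isTRUE(x$degenerate)) " [degenerate: flat data]" else ""))
  invisible(x)
}
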