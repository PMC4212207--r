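#' Boltzmann fit result
#'
#' @param v_mid,z Fitted midpoint (mV) and apparent valence (e0).
#' @param se_v_mid,se_z Asymptotic standard errors.
#' @param rss Residual sum of squares.
#' @param converged Logical.
#' @param n_points Number of fitted points.
#' @param temperature Kelvin used for F/RT.
#' @return A \code{boltzmann_fit} object.
#' @export
boltzmann_fit <- function(v_mid, z, se_v_mid = NA_real_, se_z = NA_real_,
                          rss = NA_real_, converged = TRUE,
                          n_points = NA_integer_, temperature = 298) {
  if (z <= 0) stop("z must be > 0")
  if (!is.na(rss) && rss < 0) stop("rss must be >= 0")
  structure(list(v_mid = v_mid, z = z, se_v_mid = se_v_mid, se_z = se_z,
                 rss = rss, converged = converged,
                 n_points = as.integer(n_points), temperature = temperature),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<Boltzmann fit> V_mid = %.2f %s mV, Z = %.2f %s (n = %d%s)\n",
              x$v_mid,
              if (is.na(x$se_v_mid)) "" else sprintf("± %.2f", x$se_v_mid),
              x$z,
              if (is.na(x$se_z)) "" else sprintf("± %.2f", x$se_z),
              x$n_points,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

# first half-max crossing (in protocol order) by linear interpolation
.half_crossing <- function(v, y, level = 0.5) {
  above <- y >= level
  k <- which(above[-1] != above[-length(above)])
  if (!length(k)) return(v[which.min(abs(y - level))])
  k <- k[1]
  v[k] + (level - y[k]) * (v[k + 1] - v[k]) / (y[k + 1] - y[k])
}

#' Fit the two-state Boltzmann equation to an activation curve
#'
#' Nonlinear least squares on (V_mid, Z) minimizing
#' \eqn{\sum (y - 1/(1+e^{-ZF(V - V_{mid})/RT}))^2} by Levenberg-Marquardt
#' with an analytic Jacobian. V_mid is initialized from linear interpolation
#' of the first half-maximum crossing in protocol order; Z from the 25-75%
#' voltage spread (\eqn{Z = 2\ln 3 \cdot RT/F / (V_{75} - V_{25})}). Z is
#' bounded to (0.1, 20]. Standard errors are the asymptotic values from the
#' Jacobian at the optimum.
#'
#' @param curve An \code{\link{activation_curve}} with at least 4 distinct
#'   voltages straddling the half-activation point.
#' @param temperature Kelvin.
#' @param weights Optional per-point weights (e.g. 1/SEM^2).
#' @return A \code{\link{boltzmann_fit}}.
#' @export
#' @examples
#' v <- seq(-110, 80, 10)
#' fit_boltzmann(activation_curve(v, boltzmann(v, -71, 4.2) /
#'                                   max(boltzmann(v, -71, 4.2))))
fit_boltzmann <- function(curve, temperature = 298, weights = NULL) {
  stopifnot(inherits(curve, "activation_curve"))
  v <- curve$step_voltage
  y <- curve$normalized_tail
  if (length(unique(v)) < 4)
    stop("need at least 4 distinct voltages to fit")
  if (diff(range(y)) < 0.2)
    stop("degenerate activation curve: range of normalized tails < 0.2")
  if (is.null(weights)) weights <- rep(1, length(y))
  w <- sqrt(weights)
  kT <- thermal_voltage(temperature)

  v_mid0 <- .half_crossing(v, y, 0.5 * (min(y) + max(y)))
  v25 <- .half_crossing(v[order(v)], y[order(v)], 0.25)
  v75 <- .half_crossing(v[order(v)], y[order(v)], 0.75)
  z0 <- if (is.finite(v75 - v25) && abs(v75 - v25) > 1e-6)
    2 * log(3) * kT / abs(v75 - v25) else 2
  z0 <- min(max(z0, 0.11), 20)

  resid_fn <- function(p) {
    w * (y - 1 / (1 + exp(-p[["z"]] * (v - p[["v_mid"]]) / kT)))
  }
  jac_fn <- function(p) {
    e <- exp(-p[["z"]] * (v - p[["v_mid"]]) / kT)
    f <- 1 / (1 + e)
    d <- e * f^2 # d f / d(exponent argument)
    cbind(v_mid = -w * (-d * p[["z"]] / kT),
          z = -w * (d * (v - p[["v_mid"]]) / kT))
  }
  fit <- minpack.lm::nls.lm(
    par = c(v_mid = v_mid0, z = z0), fn = resid_fn, jac = jac_fn,
    lower = c(-Inf, 0.1), upper = c(Inf, 20),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-13, maxiter = 500))
  p <- stats::coef(fit)
  r <- resid_fn(p)
  rss <- sum(r^2)
  J <- jac_fn(p)
  dof <- length(y) - 2L
  se <- rep(NA_real_, 2)
  cov_try <- try(solve(crossprod(J)), silent = TRUE)
  if (!inherits(cov_try, "try-error") && dof > 0)
    se <- sqrt(pmax(diag(cov_try), 0) * rss / dof)
  converged <- fit$info %in% 1:4
  boltzmann_fit(v_mid = p[["v_mid"]], z = p[["z"]],
                se_v_mid = se[1], se_z = se[2], rss = rss,
                converged = converged, n_points = length(y),
                temperature = temperature)
}

#' Aggregate activation curves across bilayers
#'
#' \code{pool_then_fit}: average normalized tails per voltage across curves
#' (requiring a shared voltage grid), renormalize the mean curve to maximum 1,
#' and fit once; per-voltage SEM of the mean is reported on the curve.
#' \code{fit_then_average}: fit each curve separately and report the mean and
#' SEM of V_mid and Z across bilayers, plus the per-bilayer table.
#'
#' @param curves List of \code{\link{activation_curve}} objects.
#' @param mode \code{"pool_then_fit"} or \code{"fit_then_average"}.
#' @param temperature Kelvin.
#' @return A \code{\link{boltzmann_fit}} with attributes:
#'   \code{per_bilayer} (data.frame of per-curve fits, fit_then_average mode)
#'   or \code{pooled_curve} (the mean curve with SEM, pool_then_fit mode).
#' @export
aggregate_fits <- function(curves, mode = c("pool_then_fit",
                                            "fit_then_average"),
                           temperature = 298) {
  mode <- match.arg(mode)
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "activation_curve")))
  if (mode == "pool_then_fit") {
    grid <- curves[[1]]$step_voltage
    for (cu in curves)
      if (length(cu$step_voltage) != length(grid) ||
          any(cu$step_voltage != grid))
        stop("pool_then_fit requires a shared voltage grid across curves")
    tails <- vapply(curves, function(cu) cu$normalized_tail,
                    numeric(length(grid)))
    tails <- matrix(tails, nrow = length(grid))
    m <- rowMeans(tails)
    sem <- if (ncol(tails) > 1)
      apply(tails, 1, stats::sd) / sqrt(ncol(tails)) else rep(0, length(grid))
    scale <- max(m)
    pooled <- activation_curve(grid, m / scale, sem = sem / scale,
                               n_bilayers = length(curves))
    fit <- fit_boltzmann(pooled, temperature)
    attr(fit, "pooled_curve") <- pooled
    fit
  } else {
    fits <- lapply(curves, fit_boltzmann, temperature = temperature)
    tab <- data.frame(
      curve = seq_along(fits),
      v_mid = vapply(fits, `[[`, numeric(1), "v_mid"),
      z = vapply(fits, `[[`, numeric(1), "z"),
      rss = vapply(fits, `[[`, numeric(1), "rss"),
      converged = vapply(fits, `[[`, logical(1), "converged"))
    n <- nrow(tab)
    sem <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    out <- boltzmann_fit(v_mid = mean(tab$v_mid), z = mean(tab$z),
                         se_v_mid = sem(tab$v_mid), se_z = sem(tab$z),
                         rss = sum(tab$rss), converged = all(tab$converged),
                         n_points = sum(vapply(fits, `[[`, integer(1),
                                               "n_points")),
                         temperature = temperature)
    attr(out, "per_bilayer") <- tab
    out
  }
}

#' Shift in activation midpoint between two fits
#'
#' \code{v_mid(a) - v_mid(b)}; the sign convention matches
#' "\eqn{\Delta V_{mid}} = V_mid(condition) - V_mid(reference)".
#'
#' @param fit_a,fit_b Converged \code{\link{boltzmann_fit}} objects.
#' @return Shift in mV.
#' @export
delta_v_mid <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "boltzmann_fit"), inherits(fit_b, "boltzmann_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("both fits must have converged")
  fit_a$v_mid - fit_b$v_mid
}
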