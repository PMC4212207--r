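#' Two-state Boltzmann activation function
#'
#' Fraction of maximal activation at command voltage v:
#' \deqn{I/I_{max} = 1 / (1 + e^{-ZF(V - V_{mid})/RT})}
#' where Z is the apparent gating valence and V_mid the half-activation
#' voltage.
#'
#' @param v Command voltage(s), mV.
#' @param v_mid Half-activation voltage, mV.
#' @param z Apparent valence, elementary charges (> 0).
#' @param temperature Kelvin.
#' @return Open fraction in (0, 1).
#' @export
#' @examples
#' boltzmann(-40, v_mid = -71, z = 4.2) # 0.9938
boltzmann <- function(v, v_mid, z, temperature = 298) {
  stopifnot(z > 0)
  1 / (1 + exp(-z * (v - v_mid) / thermal_voltage(temperature)))
}

#' Two-state gating model of a voltage sensor
#'
#' Minimal kinetic model used by the simulator: open probability relaxes
#' mono-exponentially toward the Boltzmann steady state
#' \eqn{p_\infty(v) = 1/(1 + e^{-z(v - V_{mid})F/RT})} with voltage-dependent
#' time constant \eqn{\tau(v) = \tau_0 / \cosh(z_\tau (v - V_{mid}) F / 2RT)},
#' the bell-shaped relaxation time of a two-state scheme. Availability
#' (inactivation) is a static factor set by the holding voltage:
#' \eqn{a = 1/(1 + e^{(v_{hold} - V_{a})/s_a})}; with a positive slope it
#' silences channels held depolarized, which is what removes one orientation
#' from a mixed-orientation bilayer.
#'
#' @param v_mid_intrinsic Intrinsic half-activation voltage of the sensor in a
#'   charge-free symmetric membrane, mV.
#' @param z Apparent valence, elementary charges (> 0).
#' @param tau0 Relaxation time constant at \code{v_mid}, ms (> 0).
#' @param z_tau Valence controlling the voltage dependence of \eqn{\tau}.
#' @param availability_v_half Midpoint of the availability curve, mV.
#' @param availability_slope Slope factor of the availability curve, mV
#'   (nonzero; positive means depolarized holding inactivates).
#' @return A \code{gating_model} object.
#' @export
gating_model <- function(v_mid_intrinsic = -71, z = 4.2, tau0 = 10,
                         z_tau = 1, availability_v_half = 0,
                         availability_slope = 6) {
  if (z <= 0) stop("z must be > 0")
  if (tau0 <= 0) stop("tau0 must be > 0")
  if (availability_slope == 0) stop("availability_slope must be nonzero")
  structure(list(v_mid_intrinsic = v_mid_intrinsic, z = z, tau0 = tau0,
                 z_tau = z_tau, availability_v_half = availability_v_half,
                 availability_slope = availability_slope),
            class = "gating_model")
}

#' Channel population in a bilayer
#'
#' Channels incorporate into planar bilayers in both orientations;
#' \code{fraction_outside_out} sets the split (about half in practice).
#'
#' @param n_channels Number of channels (>= 1).
#' @param fraction_outside_out Fraction with the extracellular face toward the
#'   ground electrode, in [0, 1].
#' @param unitary_conductance Single-channel conductance, pS.
#' @param reversal_voltage mV (0 for symmetric K+ after equilibration).
#' @return A \code{channel_population} object.
#' @export
channel_population <- function(n_channels = 100, fraction_outside_out = 0.5,
                               unitary_conductance = 180,
                               reversal_voltage = 0) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (fraction_outside_out < 0 || fraction_outside_out > 1)
    stop("fraction_outside_out must be in [0, 1]")
  if (unitary_conductance < 0) stop("unitary_conductance must be >= 0")
  structure(list(n_channels = n_channels,
                 fraction_outside_out = fraction_outside_out,
                 unitary_conductance = unitary_conductance,
                 reversal_voltage = reversal_voltage),
            class = "channel_population")
}

#' Additive Gaussian recording noise
#'
#' @param current_sd Per-sample standard deviation, pA (>= 0).
#' @param seed Integer seed; per-sweep substreams are derived from it so that
#'   identical (inputs, seed) give bit-identical families.
#' @return A \code{noise_spec} object.
#' @export
noise_spec <- function(current_sd = 0, seed = 1L) {
  if (current_sd < 0) stop("current_sd must be >= 0")
  structure(list(current_sd = current_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Saturating lipid-specific gating offset
#'
#' The phosphatidic-acid-specific component of the activation shift: a
#' rectangular-hyperbola function of the channel-frame inner-leaflet mole
#' fraction x of primary-phosphate lipid,
#' \eqn{\Delta V = \Delta V_{max}\, x / (x + K_{1/2})}. It is zero when no
#' qualifying lipid is present on the intracellular leaflet; outer-leaflet
#' primary phosphate contributes nothing beyond its surface charge.
#'
#' @param delta_v_max Plateau of the specific offset, mV.
#' @param k_half Half-saturating mole fraction (> 0).
#' @return A \code{lipid_effect} object.
#' @export
lipid_effect <- function(delta_v_max = 30, k_half = 0.03) {
  if (k_half <= 0) stop("k_half must be > 0")
  structure(list(delta_v_max = delta_v_max, k_half = k_half),
            class = "lipid_effect")
}

# Channel-frame leaflets: an outside-out channel's intracellular side is the
# bilayer's inner leaflet; an inside-out channel sees the leaflets swapped
# (and the negated command voltage).
.channel_frame <- function(bilayer, orientation) {
  orientation <- match.arg(orientation, c("outside_out", "inside_out"))
  if (orientation == "outside_out")
    list(inner = bilayer$inner, outer = bilayer$outer, sign = 1)
  else
    list(inner = bilayer$outer, outer = bilayer$inner, sign = -1)
}

.primary_phosphate_fraction <- function(comp, registry) {
  props <- .registry_lookup(names(comp), registry)
  sum(unclass(comp)[props$primary_phosphate])
}

#' Effective activation midpoint in the command-voltage frame
#'
#' The half-activation command voltage of a channel in a given bilayer:
#' \deqn{V_{mid} = V_{mid}' + (\Phi_o - \Phi_i) + \Delta V_{specific}}
#' where \eqn{\Phi_i, \Phi_o} are the Grahame surface potentials of the
#' channel-frame inner and outer leaflets and \eqn{\Delta V_{specific}} is the
#' saturating primary-phosphate term evaluated on the channel-frame inner
#' leaflet. For an inside-out channel the leaflets are swapped and the
#' returned midpoint refers to the channel-frame voltage (the negated command
#' voltage).
#'
#' @param gating A \code{\link{gating_model}}.
#' @param bilayer A \code{\link{bilayer_spec}}.
#' @param orientation \code{"outside_out"} or \code{"inside_out"}.
#' @param effect A \code{\link{lipid_effect}} or NULL for none.
#' @param registry Lipid species table.
#' @return Midpoint voltage, mV.
#' @export
#' @examples
#' g <- gating_model(v_mid_intrinsic = -71, z = 4.2)
#' b <- bilayer_spec(inner = c(DPhPC = 1), outer = c(DPhPC = 1))
#' effective_midpoint(g, b, "outside_out")  # -71: no charge, no offset
effective_midpoint <- function(gating, bilayer,
                               orientation = c("outside_out", "inside_out"),
                               effect = NULL,
                               registry = default_lipid_registry()) {
  stopifnot(inherits(gating, "gating_model"), inherits(bilayer, "bilayer_spec"))
  frame <- .channel_frame(bilayer, orientation)
  phi_i <- grahame_potential(charge_density(frame$inner, registry),
                             bilayer$electrolyte_molar, bilayer$temperature)
  phi_o <- grahame_potential(charge_density(frame$outer, registry),
                             bilayer$electrolyte_molar, bilayer$temperature)
  dv_specific <- 0
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "lipid_effect"))
    x <- .primary_phosphate_fraction(frame$inner, registry)
    if (x > 0) dv_specific <- effect$delta_v_max * x / (x + effect$k_half)
  }
  gating$v_mid_intrinsic + (phi_o - phi_i) + dv_specific
}
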