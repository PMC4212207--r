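# Grahame-relation leaflet electrostatics.
#
# Surface potential and surface charge density are linked, for a symmetric
# monovalent electrolyte, by
#   Phi = (2 k_B T / e0) * asinh(136 * sigma / sqrt(c))
# with Phi in mV, sigma in elementary charges per A^2 and c in M. The
# prefactor 2 k_B T / e0 is 51.39 mV at 298 K. The constant 136
# (A^2 M^(1/2) per e0) is used verbatim rather than re-derived from the
# solvent permittivity, so that published charge-density estimates reproduce
# bit-for-bit.
.GRAHAME_CONST <- 136

#' Leaflet surface charge density from a lipid composition
#'
#' Mole-fraction-weighted head-group charge divided by mole-fraction-weighted
#' molecular area: \eqn{\sigma = \sum_i x_i z_i / \sum_i x_i A_i}, in
#' elementary charges per \eqn{\mathrm{\AA}^2} (signed; anionic lipids give
#' negative values).
#'
#' @param comp A \code{\link{leaflet_composition}} (or named fraction vector).
#' @param registry Lipid species table; see \code{\link{default_lipid_registry}}.
#' @return Charge density in e0 per A^2.
#' @export
#' @examples
#' charge_density(c(DPhPC = 1))                      # 0
#' charge_density(c(DPhPC = 1 - 0.0909, POPG = 0.0909)) # ~ -1.14e-3
charge_density <- function(comp, registry = default_lipid_registry()) {
  if (!inherits(comp, "leaflet_composition")) comp <- leaflet_composition(comp)
  props <- .registry_lookup(names(comp), registry)
  x <- unclass(comp)
  sum(x * props$charge) / sum(x * props$area)
}

#' Surface potential from charge density (Grahame relation)
#'
#' @param sigma Surface charge density in elementary charges per A^2 (signed).
#' @param c Monovalent electrolyte concentration, M.
#' @param temperature Kelvin.
#' @return Surface potential in mV (same sign as \code{sigma}).
#' @export
#' @examples
#' grahame_potential(-1.136e-3, c = 0.15) # about -20 mV
grahame_potential <- function(sigma, c = 0.15, temperature = 298) {
  if (any(c <= 0)) stop("electrolyte concentration must be > 0")
  2 * thermal_voltage(temperature) * asinh(.GRAHAME_CONST * sigma / sqrt(c))
}

#' Charge density from surface potential (inverse Grahame relation)
#'
#' Closed-form inverse of \code{\link{grahame_potential}}:
#' \eqn{\sigma = (\sqrt{c}/136)\,\sinh(\Phi e_0 / 2 k_B T)}.
#'
#' @param phi Surface potential in mV.
#' @inheritParams grahame_potential
#' @return Charge density in e0 per A^2.
#' @export
#' @examples
#' charge_density_from_potential(20, c = 0.15) # ~1.14e-3 e0/A^2, 1 charge / ~880 A^2
charge_density_from_potential <- function(phi, c = 0.15, temperature = 298) {
  if (any(c <= 0)) stop("electrolyte concentration must be > 0")
  sqrt(c) / .GRAHAME_CONST * sinh(phi / (2 * thermal_voltage(temperature)))
}

#' Per-leaflet surface potentials and the predicted gating-voltage offset
#'
#' Computes the surface charge density and Grahame surface potential of each
#' leaflet, and the offset that unequal surface potentials impose on the
#' command-voltage activation midpoint. The voltage the sensor feels is
#' \eqn{V_{mem} = (V_i - V_o) + (\Phi_i - \Phi_o)}, so half-activation is
#' observed at a command voltage shifted by \eqn{\Phi_o - \Phi_i}: negative
#' charge confined to the outer leaflet shifts V_mid negative, negative charge
#' on the inner leaflet shifts it positive.
#'
#' @param bilayer A \code{\link{bilayer_spec}}.
#' @param registry Lipid species table.
#' @return A \code{surface_potentials} list: \code{sigma_inner},
#'   \code{sigma_outer} (e0/A^2), \code{phi_inner}, \code{phi_outer} (mV) and
#'   \code{predicted_offset} = \code{phi_outer - phi_inner} (mV).
#' @export
#' @examples
#' b <- bilayer_spec(inner = c(DPhPC = 0.91, POPA = 0.09), outer = c(DPhPC = 1))
#' surface_offset(b)
surface_offset <- function(bilayer, registry = default_lipid_registry()) {
  stopifnot(inherits(bilayer, "bilayer_spec"))
  s_i <- charge_density(bilayer$inner, registry)
  s_o <- charge_density(bilayer$outer, registry)
  p_i <- grahame_potential(s_i, bilayer$electrolyte_molar, bilayer$temperature)
  p_o <- grahame_potential(s_o, bilayer$electrolyte_molar, bilayer$temperature)
  structure(list(sigma_inner = s_i, sigma_outer = s_o,
                 phi_inner = p_i, phi_outer = p_o,
                 predicted_offset = p_o - p_i),
            class = "surface_potentials")
}

#' @export
print.surface_potentials <- function(x, ...) {
  cat("<surface potentials>\n")
  cat(sprintf("  inner: sigma %+.4g e0/A^2, phi %+.2f mV\n",
              x$sigma_inner, x$phi_inner))
  cat(sprintf("  outer: sigma %+.4g e0/A^2, phi %+.2f mV\n",
              x$sigma_outer, x$phi_outer))
  cat(sprintf("  predicted V_mid offset (phi_o - phi_i): %+.2f mV\n",
              x$predicted_offset))
  invisible(x)
}

#' Mole fraction of a -1 lipid needed for a given surface-potential magnitude
#'
#' Inverts the Grahame relation and converts the charge density to a mole
#' fraction of a monovalent anionic lipid of the given molecular area,
#' assuming all lipids share that area: \eqn{x = |\sigma| A}.
#'
#' @param target_offset Surface potential magnitude to produce, mV.
#' @param area Area per lipid molecule, A^2 (default 80).
#' @inheritParams grahame_potential
#' @return Mole fraction in [0, 1]; errors if the requirement exceeds x = 1.
#' @export
#' @examples
#' mole_fraction_for_offset(20) # ~0.09
mole_fraction_for_offset <- function(target_offset, area = 80, c = 0.15,
                                     temperature = 298) {
  stopifnot(area > 0)
  sigma <- charge_density_from_potential(abs(target_offset), c, temperature)
  x <- abs(sigma) * area
  if (any(x > 1))
    stop("target offset requires mole fraction > 1 (non-physical): x = ",
         format(max(x)))
  x
}
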