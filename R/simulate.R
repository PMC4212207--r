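#' Voltage-clamp sweep family
#'
#' Container for a simulated or imported sweep set: a shared time base, one
#' current trace per step voltage, the generating protocol and free-form
#' condition metadata.
#'
#' @param protocol A \code{\link{voltage_protocol}} (may be NULL for imported
#'   data whose protocol is unknown).
#' @param time Time base, ms.
#' @param traces Matrix of currents in pA, one row per step voltage.
#' @param metadata Named list of condition labels.
#' @return A \code{current_family} object.
#' @export
current_family <- function(protocol, time, traces, metadata = list()) {
  traces <- as.matrix(traces)
  if (ncol(traces) != length(time))
    stop("traces must have one column per time sample")
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "voltage_protocol"))
    if (nrow(traces) != length(protocol$step_voltages))
      stop("traces must have one row per step voltage")
  }
  structure(list(protocol = protocol, time = as.numeric(time), traces = traces,
                 metadata = metadata),
            class = "current_family")
}

#' @export
print.current_family <- function(x, ...) {
  cat(sprintf("<current family> %d sweeps x %d samples (%.4g ms)\n",
              nrow(x$traces), ncol(x$traces), max(x$time)))
  if (!is.null(x$protocol)) print(x$protocol)
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(
      x$metadata, function(v) paste(format(v), collapse = ","))),
      sep = "=", collapse = "; "), "\n")
  invisible(x)
}

# tau(v) for the two-state relaxation; bell-shaped around the midpoint.
.gating_tau <- function(gating, v, v_mid_eff, kT) {
  gating$tau0 / cosh(gating$z_tau * (v - v_mid_eff) / (2 * kT))
}

# Closed-form open-probability time course of one orientation subpopulation
# over the holding/step/tail epochs of one sweep, in the channel frame
# (voltages already sign-adjusted). Channels are assumed equilibrated at the
# holding voltage.
.open_probability_sweep <- function(gating, v_mid_eff, v_hold, v_step, v_tail,
                                    ep, temperature) {
  kT <- thermal_voltage(temperature)
  p_inf <- function(v) 1 / (1 + exp(-gating$z * (v - v_mid_eff) / kT))
  p <- numeric(ep$n)
  # holding: at steady state
  p0 <- p_inf(v_hold)
  p[seq_len(ep$n_hold)] <- p0
  # step: relax from p0 toward p_inf(v_step)
  te_step <- seq_len(ep$n_step) * ep$dt
  pinf_s <- p_inf(v_step)
  tau_s <- .gating_tau(gating, v_step, v_mid_eff, kT)
  p_step <- pinf_s + (p0 - pinf_s) * exp(-te_step / tau_s)
  p[ep$n_hold + seq_len(ep$n_step)] <- p_step
  # tail: relax from end-of-step p toward p_inf(v_tail)
  p_end <- p_step[ep$n_step]
  te_tail <- seq_len(ep$n_tail) * ep$dt
  pinf_t <- p_inf(v_tail)
  tau_t <- .gating_tau(gating, v_tail, v_mid_eff, kT)
  p[ep$n_hold + ep$n_step + seq_len(ep$n_tail)] <-
    pinf_t + (p_end - pinf_t) * exp(-te_tail / tau_t)
  p
}

.availability <- function(gating, v_hold) {
  1 / (1 + exp((v_hold - gating$availability_v_half) /
                 gating$availability_slope))
}

#' Simulate a planar-bilayer voltage-clamp current family
#'
#' Population-mean two-state gating with mixed channel orientations.
#' Outside-out channels see the command voltage; inside-out channels see its
#' negative and the bilayer leaflets swapped, so each orientation has its own
#' effective midpoint (surface potentials plus any primary-phosphate-specific
#' offset) and its own static availability evaluated at the holding voltage in
#' the channel frame — holding at -110 mV leaves outside-out channels
#' available while inactivating the inside-out subpopulation, and vice versa.
#' Within each epoch of constant voltage the open probability follows the
#' closed form \eqn{p(t) = p_\infty + (p_0 - p_\infty) e^{-t/\tau}}. The
#' current is ohmic, \eqn{i = a\, n\, \gamma (V_{cmd} - V_{rev})\, p(t)}
#' summed over subpopulations, with inward current negative; optional additive
#' Gaussian noise uses one substream per sweep derived from the seed.
#'
#' @param gating A \code{\link{gating_model}}.
#' @param population A \code{\link{channel_population}}.
#' @param bilayer A \code{\link{bilayer_spec}}.
#' @param effect A \code{\link{lipid_effect}} or NULL.
#' @param protocol A \code{\link{voltage_protocol}}.
#' @param noise A \code{\link{noise_spec}}.
#' @param registry Lipid species table.
#' @return A \code{\link{current_family}}; \code{metadata$truth} records the
#'   generating parameters (including each orientation's effective midpoint)
#'   for parameter-recovery tests.
#' @export
#' @examples
#' fam <- simulate_family(gating_model(), channel_population(),
#'                        bilayer_spec(c(DPhPC = 1), c(DPhPC = 1)),
#'                        protocol = voltage_protocol(-110, seq(-110, 80, 10)))
simulate_family <- function(gating, population, bilayer, effect = NULL,
                            protocol = voltage_protocol(-110, seq(-110, 80, 10)),
                            noise = noise_spec(0, 1L),
                            registry = default_lipid_registry()) {
  stopifnot(inherits(gating, "gating_model"),
            inherits(population, "channel_population"),
            inherits(bilayer, "bilayer_spec"),
            inherits(protocol, "voltage_protocol"),
            inherits(noise, "noise_spec"))
  ep <- .protocol_epochs(protocol)
  steps <- protocol$step_voltages
  temperature <- bilayer$temperature

  subpops <- list(
    outside_out = population$n_channels * population$fraction_outside_out,
    inside_out = population$n_channels * (1 - population$fraction_outside_out))
  v_mid_eff <- vapply(names(subpops), function(o)
    effective_midpoint(gating, bilayer, o, effect, registry), numeric(1))

  # command voltage at each sample, per sweep epoch layout
  traces <- matrix(0, nrow = length(steps), ncol = ep$n)
  avail <- numeric(0)
  for (orient in names(subpops)) {
    n_sub <- subpops[[orient]]
    if (n_sub <= 0) next
    s <- if (orient == "outside_out") 1 else -1
    a <- .availability(gating, s * protocol$holding_voltage)
    avail[orient] <- a
    if (a == 0) next
    for (k in seq_along(steps)) {
      p <- .open_probability_sweep(
        gating, v_mid_eff[[orient]],
        v_hold = s * protocol$holding_voltage,
        v_step = s * steps[k],
        v_tail = s * protocol$tail_voltage,
        ep = ep, temperature = temperature)
      v_cmd <- c(rep(protocol$holding_voltage, ep$n_hold),
                 rep(steps[k], ep$n_step),
                 rep(protocol$tail_voltage, ep$n_tail))
      # pS * mV = fA; divide by 1000 for pA
      traces[k, ] <- traces[k, ] +
        a * n_sub * population$unitary_conductance *
        (v_cmd - population$reversal_voltage) * p / 1000
    }
  }

  if (noise$current_sd > 0) {
    set.seed(noise$seed)
    sweep_seeds <- sample.int(.Machine$integer.max, length(steps))
    for (k in seq_along(steps)) {
      set.seed(sweep_seeds[k])
      traces[k, ] <- traces[k, ] + stats::rnorm(ep$n, sd = noise$current_sd)
    }
  }

  current_family(
    protocol, ep$time, traces,
    metadata = list(
      truth = list(gating = unclass(gating), population = unclass(population),
                   effect = if (!is.null(effect)) unclass(effect),
                   v_mid_eff = as.list(v_mid_eff),
                   availability = as.list(avail),
                   noise = unclass(noise),
                   temperature = temperature)))
}

#' Add lipid to one leaflet by vesicle fusion
#'
#' Models vesicle fusion, which deposits the vesicle lipid predominantly into
#' the leaflet facing the side of addition: the named leaflet is renormalized
#' to contain the added species at \code{added_fraction}, with an optional
#' leakage fraction delivered to the opposite leaflet (default 0).
#'
#' @param bilayer A \code{\link{bilayer_spec}}.
#' @param side \code{"inner"}/\code{"cis"} or \code{"outer"}/\code{"trans"}.
#' @param species Lipid name (must be in the registry when the bilayer is used
#'   downstream).
#' @param added_fraction Mole fraction of the added species in the modified
#'   leaflet, in [0, 1).
#' @param leakage Fraction of \code{added_fraction} also delivered to the
#'   opposite leaflet.
#' @return A new \code{\link{bilayer_spec}}.
#' @export
#' @examples
#' b <- bilayer_spec(c(DPhPC = 1), c(DPhPC = 1))
#' fuse_vesicles(b, "inner", "POPA", 0.09)
fuse_vesicles <- function(bilayer, side, species, added_fraction,
                          leakage = 0) {
  stopifnot(inherits(bilayer, "bilayer_spec"))
  if (added_fraction < 0 || added_fraction >= 1)
    stop("added_fraction must be in [0, 1)")
  if (leakage < 0 || leakage > 1) stop("leakage must be in [0, 1]")
  side <- .resolve_side(side)
  other <- setdiff(c("inner", "outer"), side)

  mix <- function(comp, frac) {
    if (frac == 0) return(comp)
    x <- unclass(comp) * (1 - frac)
    x[species] <- (if (species %in% names(x)) x[[species]] else 0) + frac
    leaflet_composition(x)
  }
  out <- bilayer
  out[[side]] <- mix(bilayer[[side]], added_fraction)
  out[[other]] <- mix(bilayer[[other]], added_fraction * leakage)
  out
}

#' Phospholipase D1 conversion of PC to PA on one leaflet
#'
#' PLD1 cleaves the choline head-group of phosphatidylcholine, generating
#' phosphatidic acid on the side to which the enzyme is added. Modeled as
#' first-order decay of every choline-head-group species (PC lipids and
#' sphingomyelin are treated as PC-class substrates only if named "..PC") on
#' the treated leaflet: \eqn{x_{PC}(t) = x_{PC}(0) e^{-rt}}, with the
#' converted fraction added to the corresponding PA species
#' (name with "PC" replaced by "PA"); total mole fraction is conserved.
#'
#' @param bilayer A \code{\link{bilayer_spec}}.
#' @param side \code{"inner"}/\code{"cis"} or \code{"outer"}/\code{"trans"}.
#' @param rate First-order conversion rate, per minute (>= 0).
#' @param t Exposure time, minutes (>= 0).
#' @return A new \code{\link{bilayer_spec}}.
#' @export
#' @examples
#' b <- bilayer_spec(c(DPhPC = 1), c(DPhPC = 1))
#' pld_time_course(b, "inner", rate = log(2) / 10, t = 10) # half converted
pld_time_course <- function(bilayer, side, rate, t) {
  stopifnot(inherits(bilayer, "bilayer_spec"))
  if (rate < 0) stop("rate must be >= 0")
  if (t < 0) stop("t must be >= 0")
  side <- .resolve_side(side)
  x <- unclass(bilayer[[side]])
  pc <- grepl("PC$", names(x))
  if (any(pc) && rate * t > 0) {
    remaining <- exp(-rate * t)
    for (nm in names(x)[pc]) {
      converted <- x[[nm]] * (1 - remaining)
      pa_name <- sub("PC$", "PA", nm)
      x[[nm]] <- x[[nm]] * remaining
      x[pa_name] <- (if (pa_name %in% names(x)) x[[pa_name]] else 0) + converted
    }
  }
  out <- bilayer
  out[[side]] <- leaflet_composition(x)
  out
}
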