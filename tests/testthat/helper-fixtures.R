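# Shared fixtures and independent oracles.

# Symmetric DPhPC reference bilayer.
dphpc_bilayer <- function() bilayer_spec(c(DPhPC = 1), c(DPhPC = 1))

# Standard forward family protocol: -110 to +80 mV in 10 mV steps.
fig_forward_protocol <- function(holding = -110, top = 80,
                                 step_duration = 100, dt = 0.5)
  voltage_protocol(holding, seq(holding, top, by = 10),
                   holding_duration = 50, step_duration = step_duration,
                   tail_duration = 50, sample_interval = dt)

default_gating <- function(...) {
  args <- utils::modifyList(
    list(v_mid_intrinsic = -71, z = 4.2, tau0 = 10, z_tau = 1,
         availability_v_half = 0, availability_slope = 6),
    list(...))
  do.call(gating_model, args)
}

# Independent oracle: explicit-Euler integration of dp/dt = (p_inf - p)/tau
# at a step 1000x finer than the simulator's sample interval, for one epoch
# of constant voltage in the channel frame.
euler_p_end <- function(gating, v_mid_eff, p0, v, t_end, h,
                        temperature = 298) {
  kT <- kvlipid::thermal_voltage(temperature)
  p_inf <- 1 / (1 + exp(-gating$z * (v - v_mid_eff) / kT))
  tau <- gating$tau0 / cosh(gating$z_tau * (v - v_mid_eff) / (2 * kT))
  n <- round(t_end / h)
  p <- p0
  for (i in seq_len(n)) p <- p + h * (p_inf - p) / tau
  p
}

# Closed-form open probability at the end of the step epoch (used where the
# analytic time course is itself the reference for extraction).
p_end_of_step <- function(gating, v_mid_eff, v_hold, v_step, step_duration,
                          temperature = 298) {
  kT <- kvlipid::thermal_voltage(temperature)
  p_inf <- function(v) 1 / (1 + exp(-gating$z * (v - v_mid_eff) / kT))
  tau <- gating$tau0 / cosh(gating$z_tau * (v_step - v_mid_eff) / (2 * kT))
  p_inf(v_step) + (p_inf(v_hold) - p_inf(v_step)) * exp(-step_duration / tau)
}
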