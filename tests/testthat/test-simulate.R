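test_that("protocol validation enforces monotone steps and resolvable sampling", {
  expect_error(voltage_protocol(-110, c(-110, -90, -100)), "monoton|increasing")
  expect_error(voltage_protocol(-110, seq(-110, 80, 10), step_duration = -1),
               "positive")
  expect_error(voltage_protocol(-110, seq(-110, 80, 10), step_duration = 10,
                                sample_interval = 2), "sample_interval")
  rev <- voltage_protocol(110, seq(110, -80, -10))
  expect_identical(rev$step_voltages[1], 110)
})

test_that("simulation is deterministic for identical inputs and seed", {
  g <- default_gating(); pop <- channel_population(); b <- dphpc_bilayer()
  pr <- fig_forward_protocol()
  f1 <- simulate_family(g, pop, b, NULL, pr, noise_spec(2, 7L))
  f2 <- simulate_family(g, pop, b, NULL, pr, noise_spec(2, 7L))
  expect_identical(f1$traces, f2$traces)
  f3 <- simulate_family(g, pop, b, NULL, pr, noise_spec(2, 8L))
  expect_false(identical(f1$traces, f3$traces))
})

test_that("open probability stays within [0,1] across the family", {
  g <- default_gating()
  ep <- kvlipid:::.protocol_epochs(fig_forward_protocol())
  for (v_step in c(-110, -71, 0, 80)) {
    p <- kvlipid:::.open_probability_sweep(
      g, v_mid_eff = -71, v_hold = -110, v_step = v_step, v_tail = -110,
      ep = ep, temperature = 298)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("end-of-step open probability matches a 1000x-finer Euler oracle", {
  g <- default_gating()
  dt <- 0.5
  pr <- voltage_protocol(-110, seq(-110, 80, 10), step_duration = 150,
                         sample_interval = dt)
  ep <- kvlipid:::.protocol_epochs(pr)
  kT <- thermal_voltage(298)
  p_hold <- 1 / (1 + exp(-g$z * (-110 + 71) / kT))
  for (v_step in c(-90, -71, -50, 0, 80)) {
    p <- kvlipid:::.open_probability_sweep(
      g, v_mid_eff = -71, v_hold = -110, v_step = v_step, v_tail = -110,
      ep = ep, temperature = 298)
    p_end <- p[ep$n_hold + ep$n_step]
    oracle <- euler_p_end(g, v_mid_eff = -71, p0 = p_hold, v = v_step,
                          t_end = pr$step_duration, h = dt / 1000)
    expect_equal(p_end, oracle, tolerance = 1e-9)
  }
})

test_that("saturating steps open fully and tails are inward", {
  g <- default_gating(z = 12) # steep valence: saturation limit
  pop <- channel_population(100, 1, 180, 0)
  pr <- voltage_protocol(-110, c(-110, 80), step_duration = 200)
  fam <- simulate_family(g, pop, dphpc_bilayer(), NULL, pr)
  ep <- kvlipid:::.protocol_epochs(pr)
  i_end_step <- fam$traces[2, ep$n_hold + ep$n_step]
  # fully open at +80: current = n * gamma * V / 1000
  expect_equal(i_end_step, 100 * 180 * 80 / 1000, tolerance = 1e-3)
  i_tail_start <- fam$traces[2, ep$n_hold + ep$n_step + 1L]
  expect_lt(i_tail_start, 0) # inward at the negative tail voltage
})

test_that("inside-out channels are inactivated at a negative holding voltage", {
  g <- default_gating() # availability midpoint 0 mV, positive slope
  b <- dphpc_bilayer()
  pr <- fig_forward_protocol()
  io_only <- channel_population(100, 0, 180, 0)
  fam <- simulate_family(g, io_only, b, NULL, pr)
  expect_lt(max(abs(fam$traces)), 1e-4) # essentially zero current
  oo_only <- channel_population(100, 1, 180, 0)
  fam_oo <- simulate_family(g, oo_only, b, NULL, pr)
  expect_gt(max(abs(fam_oo$traces)), 100)
  # mirrored: positive holding silences the outside-out subpopulation
  pr_rev <- voltage_protocol(110, seq(110, -80, -10))
  fam_rev_oo <- simulate_family(g, oo_only, b, NULL, pr_rev)
  expect_lt(max(abs(fam_rev_oo$traces)), 1e-4)
})

test_that("forward outside-out and reverse inside-out curves agree in symmetric membranes", {
  g <- default_gating()
  b <- dphpc_bilayer()
  fwd <- simulate_family(g, channel_population(100, 1, 180, 0), b, NULL,
                         voltage_protocol(-150, seq(-150, 80, 10)))
  rev <- simulate_family(g, channel_population(100, 0, 180, 0), b, NULL,
                         voltage_protocol(150, seq(150, -80, -10)))
  f_fwd <- fit_boltzmann(extract_tails(fwd))
  cr <- extract_tails(rev)
  # inside-out channels respond to the negated command voltage
  f_rev <- fit_boltzmann(activation_curve(-cr$step_voltage,
                                          cr$normalized_tail))
  expect_lt(abs(f_fwd$v_mid - f_rev$v_mid), 0.1)
})

test_that("simulating with imposed leaflet potentials shifts V_mid by phi_o - phi_i", {
  g <- default_gating()
  pop <- channel_population()
  pr <- voltage_protocol(-150, seq(-150, 80, 10))
  b_ref <- dphpc_bilayer()
  cases <- list(
    outer = bilayer_spec(inner = c(DPhPC = 1),
                         outer = c(DPhPC = 0.91, POPG = 0.09)),
    inner = bilayer_spec(inner = c(DPhPC = 0.91, POPG = 0.09),
                         outer = c(DPhPC = 1)))
  f_ref <- fit_boltzmann(extract_tails(
    simulate_family(g, pop, b_ref, NULL, pr)))
  for (b in cases) {
    predicted <- surface_offset(b)$predicted_offset
    f <- fit_boltzmann(extract_tails(simulate_family(g, pop, b, NULL, pr)))
    expect_lt(abs(delta_v_mid(f, f_ref) - predicted), 0.1)
  }
})

test_that("the generating truth records per-orientation effective midpoints", {
  g <- default_gating()
  b <- bilayer_spec(inner = c(DPhPC = 0.91, POPA = 0.09), outer = c(DPhPC = 1))
  eff <- lipid_effect(30, 0.03)
  fam <- simulate_family(g, channel_population(), b, eff,
                         fig_forward_protocol())
  truth <- fam$metadata$truth
  expect_equal(truth$v_mid_eff$outside_out,
               effective_midpoint(g, b, "outside_out", eff))
  expect_equal(truth$v_mid_eff$inside_out,
               effective_midpoint(g, b, "inside_out", eff))
})
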