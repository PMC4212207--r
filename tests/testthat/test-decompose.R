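test_that("decomposition splits observed shifts with machine-exact additivity", {
  x <- 0.09
  b <- bilayer_spec(inner = c(DPhPC = 1 - x, POPA = x), outer = c(DPhPC = 1))
  d <- decompose_shift(50, b, condition = "inner-leaflet PA")
  expect_identical(d$observed_shift, d$surface_component + d$specific_component)
  expect_equal(d$surface_component, 20, tolerance = 0.05)
  expect_equal(d$specific_component, 30, tolerance = 0.05)

  # observed equals the predicted surface component -> specific is 0
  d0 <- decompose_shift(d$surface_component, b)
  expect_equal(d0$specific_component, 0, tolerance = 1e-12)

  # intracellular POPS-calibrated example: observed +58 with x = 0.09 PA
  d58 <- decompose_shift(58, b)
  expect_equal(d58$surface_component, 19.6, tolerance = 0.05)
  expect_equal(d58$specific_component, 38.4, tolerance = 0.05)

  # a reference bilayer subtracts its own predicted offset
  dref <- decompose_shift(50, b, reference = b)
  expect_identical(dref$surface_component, 0)
})

test_that("symmetric-membrane comparisons are interpreted as wholly specific", {
  expect_equal(specific_shift_symmetric(-40, -71), 31) # ~ +30 mV PA-specific
  expect_equal(specific_shift_symmetric(-6, -25), 19)  # KvAP, ~ +17/18 mV
  expect_identical(specific_shift_symmetric(-40, -40), 0)
})

test_that("saturation fit recovers the published titration with K1/2 below 0.1", {
  x <- c(0, 0.05, 0.1, 0.25, 0.5, 1)
  v <- c(-71, -60, -43, -40, -33, -31)
  fit <- fit_saturation(x, v)
  expect_false(fit$degenerate)
  expect_lt(fit$k_half, 0.1)       # "by 0.1 it is nearly complete"
  expect_gt(fit$delta_v_max, 30)
  expect_lt(abs(fit$baseline_v_mid + 71), 3)
})

test_that("saturation fit handles flat data and exact hyperbolic data", {
  x <- c(0, 0.05, 0.2, 0.8)
  flat <- fit_saturation(x, rep(-70, 4))
  expect_true(flat$degenerate)
  expect_identical(flat$delta_v_max, 0)
  # exact data: baseline at x=0, near-plateau at x >> k_half
  y <- -71 + 30 * x / (x + 0.02)
  f <- fit_saturation(x, y)
  expect_equal(f$baseline_v_mid, -71, tolerance = 1e-6)
  expect_equal(f$delta_v_max, 30, tolerance = 1e-6)
  expect_equal(f$k_half, 0.02, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  # Hill extension reduces to the hyperbola on one-site data
  fh <- fit_saturation(x, y, hill = TRUE)
  expect_equal(fh$hill, 1, tolerance = 1e-3)
  expect_error(fit_saturation(c(0, 0.1), c(-71, -40)), "at least 3")
})

test_that("saturation parameters are recovered from seeded noisy titrations", {
  x <- c(0, 0.05, 0.1, 0.25, 0.5, 1)
  dmax <- 40; k <- 0.09; base <- -71; n_rep <- 8
  set.seed(101)
  v <- base + dmax * x / (x + k) +
    rowMeans(matrix(rnorm(length(x) * n_rep, sd = 2), ncol = n_rep))
  fit <- fit_saturation(x, v)
  expect_lt(abs(fit$delta_v_max - dmax) / dmax, 0.2)
  expect_lt(abs(fit$k_half - k) / k, 0.2)
})

test_that("simulate-fit-decompose recovers an imposed specific component", {
  g <- default_gating()
  pop <- channel_population()
  pr <- voltage_protocol(-150, seq(-150, 80, 10))
  x <- 0.09
  b_ref <- dphpc_bilayer()
  b_pa <- bilayer_spec(inner = c(DPhPC = 1 - x, POPA = x), outer = c(DPhPC = 1))
  eff <- lipid_effect(delta_v_max = 30, k_half = 0.01)
  truth_specific <- 30 * x / (x + 0.01)

  f_ref <- fit_boltzmann(extract_tails(simulate_family(g, pop, b_ref, NULL, pr)))
  f_pa <- fit_boltzmann(extract_tails(simulate_family(g, pop, b_pa, eff, pr)))
  d <- decompose_shift(delta_v_mid(f_pa, f_ref), b_pa)
  expect_lt(abs(d$specific_component - truth_specific), 1)

  # noisy replicates: recovered specific component within 2 SEM of truth
  set.seed(17)
  shifts <- replicate(8, {
    fr <- fit_boltzmann(extract_tails(
      simulate_family(g, pop, b_ref, NULL, pr, noise_spec(3, sample.int(1e6, 1)))))
    fp <- fit_boltzmann(extract_tails(
      simulate_family(g, pop, b_pa, eff, pr, noise_spec(3, sample.int(1e6, 1)))))
    decompose_shift(delta_v_mid(fp, fr), b_pa)$specific_component
  })
  sem <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts) - truth_specific), 2 * sem + 0.1)
})
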