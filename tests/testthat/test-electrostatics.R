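test_that("charge density is the fraction-weighted charge over area", {
  expect_identical(charge_density(c(DPhPC = 1)), 0)
  # one POPG per 11 DPhPC: about one negative charge per 880 A^2
  x <- 1 / 11
  expect_equal(charge_density(c(DPhPC = 1 - x, POPG = x)),
               -x / 80, tolerance = 1e-12)
  expect_equal(charge_density(c(DPhPC = 1 - 0.0909, POPG = 0.0909)),
               -1.136e-3, tolerance = 1e-3)
  # 1:1 mix of a -1 lipid with DPhPC, all areas 80
  expect_equal(charge_density(c(DPhPC = 0.5, POPS = 0.5)), -6.25e-3,
               tolerance = 1e-12)
  expect_error(charge_density(c(NotALipid = 1)), "unknown lipid")
})

test_that("charge density is linear in mole fraction at equal areas", {
  xs <- seq(0, 1, by = 0.1)
  sig <- vapply(xs, function(x)
    charge_density(c(DPhPC = 1 - x, POPA = x)), numeric(1))
  expect_equal(sig, -xs / 80, tolerance = 1e-12)
})

test_that("Grahame potential matches published inversion pair", {
  expect_identical(grahame_potential(0, 0.15), 0)
  expect_equal(grahame_potential(-1.136e-3, c = 0.15, temperature = 298),
               -20.0, tolerance = 2e-3)
  expect_equal(grahame_potential(1 / 900, c = 0.15, temperature = 298),
               19.6, tolerance = 2e-3)
  expect_error(grahame_potential(1e-3, c = 0), "must be > 0")
})

test_that("Grahame relation is antisymmetric and screened by electrolyte", {
  sig <- c(1e-4, 1e-3, 5e-3, 1e-2)
  expect_identical(grahame_potential(-sig, 0.15), -grahame_potential(sig, 0.15))
  cs <- c(0.015, 0.05, 0.15, 0.5, 1.5)
  phis <- abs(vapply(cs, function(cc) grahame_potential(2e-3, cc), numeric(1)))
  expect_true(all(diff(phis) < 0))
})

test_that("Grahame linear limit matches the small-charge expansion", {
  kT2 <- 2 * thermal_voltage(298)
  c0 <- 0.15
  sig <- 0.04 * sqrt(c0) / 136 # |136 sigma / sqrt(c)| = 0.04 < 0.05
  expect_equal(grahame_potential(sig, c0), kT2 * 136 * sig / sqrt(c0),
               tolerance = 1e-3)
})

test_that("forward and inverse Grahame forms round-trip to 1e-12", {
  expect_identical(charge_density_from_potential(0, 0.15), 0)
  sig <- seq(-0.01, 0.01, length.out = 41)
  back <- charge_density_from_potential(grahame_potential(sig, 0.15), 0.15)
  expect_equal(back, sig, tolerance = 1e-12)
  phi <- seq(-150, 150, length.out = 31)
  back_phi <- grahame_potential(charge_density_from_potential(phi, 0.15), 0.15)
  expect_equal(back_phi, phi, tolerance = 1e-12)
})

test_that("a 20 mV surface potential maps to ~0.09 mole fraction of -1 lipid", {
  sigma <- charge_density_from_potential(20, c = 0.15)
  expect_equal(1 / sigma, 880, tolerance = 0.002)   # ~1 charge per 880 A^2
  expect_equal(sigma * 80, 0.09, tolerance = 0.02)  # 1 per 11 DPhPC
  x <- mole_fraction_for_offset(20, area = 80, c = 0.15)
  expect_equal(round(x, 2), 0.09)
  expect_identical(mole_fraction_for_offset(0), 0)
  expect_error(mole_fraction_for_offset(500), "non-physical")
})

test_that("mole_fraction_for_offset chains back to the target offset", {
  for (target in c(5, 20, 60)) {
    x <- mole_fraction_for_offset(target, area = 80, c = 0.15)
    sig <- charge_density(
      leaflet_composition(c(DPhPC = 1 - x, POPG = x)))
    expect_equal(grahame_potential(sig, 0.15), -target, tolerance = 1e-9)
  }
})

test_that("surface offset follows phi_outer - phi_inner with sign antisymmetry", {
  sym <- surface_offset(bilayer_spec(c(DPhPC = 0.75, POPA = 0.25),
                                     c(DPhPC = 0.75, POPA = 0.25)))
  expect_identical(sym$predicted_offset, 0)
  x <- 0.09
  outer_only <- surface_offset(bilayer_spec(
    inner = c(DPhPC = 1), outer = c(DPhPC = 1 - x, POPG = x)))
  inner_only <- surface_offset(bilayer_spec(
    inner = c(DPhPC = 1 - x, POPG = x), outer = c(DPhPC = 1)))
  expect_equal(outer_only$predicted_offset, -19.6, tolerance = 0.01)
  expect_identical(outer_only$predicted_offset, -inner_only$predicted_offset)
  expect_identical(outer_only$predicted_offset,
                   outer_only$phi_outer - outer_only$phi_inner)
})

test_that("registry can be user-extended and validates its schema", {
  reg <- default_lipid_registry()
  expect_true(all(c("POPA", "DPhPA", "DMPA", "DOPA", "BrPOPA") %in%
                    reg$name[reg$primary_phosphate]))
  expect_false(any(c("POPG", "POPS", "PI") %in%
                     reg$name[reg$primary_phosphate]))
  tmp <- withr::local_tempfile(fileext = ".csv")
  custom <- rbind(reg, data.frame(name = "POPA2", charge = -2, area = 75,
                                  primary_phosphate = TRUE,
                                  low_confidence = TRUE))
  write.csv(custom, tmp, row.names = FALSE)
  reg2 <- read_lipid_registry(tmp)
  expect_equal(charge_density(c(POPA2 = 1), reg2), -2 / 75)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,charge\nX,-1", bad)
  expect_error(read_lipid_registry(bad), "missing columns")
})
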