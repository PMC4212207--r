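# kvlipid

Analysis of how membrane lipid composition shifts the voltage-dependent
activation of K+ (Kv) channels reconstituted into planar lipid bilayers —
for electrophysiologists and membrane biophysicists quantifying lipid
effects on voltage-sensor gating.

Activation is summarized by fitting normalized tail currents to the
two-state Boltzmann equation

    I/Imax = 1 / (1 + exp(-ZF(V - Vmid)/RT))

giving the half-activation voltage `Vmid` (mV) and apparent valence `Z`
(elementary charges). Lipid-induced shifts of `Vmid` are decomposed into:

- a **surface-charge offset**: per-leaflet charge densities
  σ = Σxᵢzᵢ / ΣxᵢAᵢ are mapped to surface potentials with the Grahame
  relation Φ = (2kBT/e₀)·asinh(136σ/√c), and the sensor feels
  V_mem = (Vᵢ − V_o) + (Φᵢ − Φ_o), so the observed midpoint moves by
  Φ_o − Φᵢ;
- a **lipid-specific offset**: the residual, which for phosphatidic acid
  acts from the inner leaflet only, requires a primary phosphate, and
  saturates as ΔVmax·x/(x + K½).

The package also includes a synthetic recording generator (mixed channel
orientations, holding-voltage-dependent availability, two-state kinetics,
seeded Gaussian noise) so the whole pipeline is testable end to end, plus
CSV/ATF sweep I/O and a command-line driver
(`system.file("scripts", "kvlipid", package = "kvlipid")` with subcommands
`simulate`, `fit`, `surface`, `decompose`, `titrate`).

## Worked example

Simulate a DPhPC bilayer before and after fusing POPA vesicles to the
intracellular leaflet at mole fraction 0.09, fit both activation curves,
and decompose the shift:

```r
library(kvlipid)

g        <- gating_model(v_mid_intrinsic = -71, z = 4.2)
pop      <- channel_population(n_channels = 100, fraction_outside_out = 0.5)
ref      <- bilayer_spec(inner = c(DPhPC = 1), outer = c(DPhPC = 1))
pa       <- fuse_vesicles(ref, side = "inner", species = "POPA",
                          added_fraction = 0.09)
protocol <- voltage_protocol(-150, seq(-150, 80, 10))
eff      <- lipid_effect(delta_v_max = 30, k_half = 0.01)

fit_ref <- fit_boltzmann(extract_tails(
  simulate_family(g, pop, ref, NULL, protocol, noise_spec(2, seed = 7))))
fit_pa  <- fit_boltzmann(extract_tails(
  simulate_family(g, pop, pa, eff, protocol, noise_spec(2, seed = 8))))
fit_ref
#> <Boltzmann fit> V_mid = -70.92 ± 0.04 mV, Z = 4.19 ± 0.03 (n = 24)
fit_pa
#> <Boltzmann fit> V_mid = -24.13 ± 0.08 mV, Z = 4.13 ± 0.05 (n = 24)

shift <- delta_v_mid(fit_pa, fit_ref)
decompose_shift(shift, pa, condition = "inner-leaflet POPA 0.09")
#> <shift decomposition> inner-leaflet POPA 0.09
#>   observed +46.8 mV = surface charge +19.8 mV + lipid-specific +27.0 mV
```

Reading the numbers: the reference membrane fits at `Vmid ≈ −71 mV`. Adding
9 mol% POPA to the intracellular leaflet shifts the midpoint about +47 mV,
of which +19.8 mV is accounted for by the screened surface potential of the
added −1 charge (Grahame relation at 0.15 M KCl) and the remaining +27 mV is
the PA-specific component — the saturating primary-phosphate effect, here
imposed at ΔVmax = 30 mV with x/(x+K½) = 0.9.

The electrostatic calibration on its own:

```r
sigma <- charge_density_from_potential(20, c = 0.15)  # 20 mV at 0.15 M
1 / sigma     # ~880 A^2 per charge (~900 to 1 significant figure)
sigma * 80    # ~0.09 mole fraction of a -1 lipid at 80 A^2/lipid
```

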