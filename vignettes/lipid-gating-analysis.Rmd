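---
title: "Quantifying lipid modulation of Kv channel activation in planar bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid modulation of Kv channel activation in planar bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvlipid)
```

## The problem

Voltage-gated K+ (Kv) channels reconstituted into planar lipid bilayers open
on depolarization with a sigmoidal voltage dependence summarized by two
numbers: the half-activation command voltage $V_{mid}$ and the apparent
gating valence $Z$. Changing the lipid composition of the bilayer shifts
$V_{mid}$, and the shifts have two distinguishable origins:

1. **A surface-charge offset.** Anionic lipids build a fixed charge layer at
   the membrane–water interface. Its screened electrostatic potential adds to
   the applied voltage inside the membrane, so the sensor feels
   $V_{mem} = (V_i - V_o) + (\Phi_i - \Phi_o)$ and half-activation is observed
   at a command voltage offset by $\Phi_o - \Phi_i$. Negative charge confined
   to the outer leaflet shifts $V_{mid}$ negative; on the inner leaflet,
   positive.
2. **A lipid-specific offset.** Phosphatidic acid (PA) — and other lipids
   carrying an unesterified, *primary* phosphate — produces an additional
   positive shift that acts only from the intracellular leaflet, saturates
   steeply with mole fraction, and cannot be explained by its $-1$ charge
   (POPG, POPS and PI carry the same charge and produce only the
   surface-charge offset).

This package implements the full quantitative chain needed to measure and
decompose these effects: tail-current extraction and Boltzmann fitting,
Grahame-relation leaflet electrostatics, shift decomposition and
dose–response fitting, plus a synthetic recording generator so that the whole
chain is testable without real recordings.

## The activation fit

Tail currents measured shortly after stepping back from each depolarization
index the open probability reached during the step. Normalized tail
amplitudes against step voltage form the activation curve, fit to the
two-state Boltzmann equation

$$\frac{I}{I_{max}} = \frac{1}{1 + e^{-ZF(V - V_{mid})/RT}}.$$

`fit_boltzmann()` uses Levenberg–Marquardt least squares with an analytic
Jacobian. Initialization is deterministic: $V_{mid}$ from linear
interpolation of the first half-maximum crossing in protocol order (a fixed
tie-break for noisy curves with multiple crossings), $Z$ from the 25–75%
voltage spread ($Z = 2\ln 3\,(RT/F)/(V_{75}-V_{25})$). $Z$ is constrained to
$(0.1, 20]$; curves with fewer than 4 distinct voltages or a normalized range
below 0.2 are rejected as degenerate rather than fit. Standard errors are the
asymptotic values from $(J^\top J)^{-1}\,\hat\sigma^2$ at the optimum.

Two aggregation modes are provided because published legends do not always
say which was used: `pool_then_fit` averages normalized tails per voltage
across bilayers (reporting the SEM) and fits once; `fit_then_average` fits
each bilayer and reports the mean ± SEM of the parameters.

**Tail window.** The measurement window is genuinely underdetermined by
"shortly after the step", so it is a parameter: the default is the mean over
2–5 ms after the tail step, which skips capacitive settling but precedes most
deactivation at the default kinetics. `peak` and single-exponential
back-extrapolation modes are selectable; on noiseless simulated data all
three agree to ~0.1%. The per-sweep baseline is the mean of the final 20% of
the holding epoch.

## Leaflet electrostatics

For a symmetric monovalent electrolyte at molarity $c$, surface charge
density $\sigma$ (elementary charges per Å$^2$) and surface potential $\Phi$
(mV) are linked by the Grahame relation

$$\Phi = \frac{2 k_B T}{e_0}\,\sinh^{-1}\!\left(\frac{136\,\sigma}{\sqrt{c}}\right),$$

with the closed-form inverse implemented alongside so the pair round-trips to
machine precision. The constant 136 (Å² M$^{1/2}$ per $e_0$) is used verbatim
rather than re-derived from the permittivity, so published charge-density
estimates are reproduced bit-for-bit. Leaflet charge density comes from the
composition as $\sigma = \sum_i x_i z_i / \sum_i x_i A_i$.

Worked inversion at the calibration point: a 20 mV potential at
$c = 0.15$ M maps to $\sigma \approx 1.14\times10^{-3}\,e_0$/Å², i.e. one
charge per ~880 Å² (≈ 900 to one significant figure), which at 80 Å² per
lipid is a mole fraction of ≈ 0.09 of a $-1$ lipid — one anionic lipid per
11 neutral ones.

```{r grahame}
sigma <- charge_density_from_potential(20, c = 0.15)
c(sigma = sigma, area_per_charge = 1 / sigma, mole_fraction = sigma * 80)
```

The packaged lipid registry assigns charges at pH 7.5: PC, PE and
sphingomyelin 0; POPA, POPG, POPS, PI and the other PA species $-1$;
cardiolipin $-2$. PA is treated as $-1$ even though its second pKa is near
physiological pH; the DOPP ($-2$) and PIP ($-3$) entries are flagged
low-confidence. Everything is overridable through a user CSV/YAML registry
(`read_lipid_registry()`). Divalent ions, Stern layers and dipole potentials
(which cancel across leaflets) are out of scope; the electrolyte defaults to
0.15 M, the post-equilibration recording condition.

**Temperature.** Recording temperature is not stated in the source data, so
the package defaults to 298 K ($RT/F = 25.68$ mV), configurable everywhere a
Boltzmann factor appears. Every calibration quantity above is insensitive to
the 298 vs 298.15 K distinction at the reported precision.

## Shift decomposition

`decompose_shift()` splits an observed $\Delta V_{mid}$ into the
electrostatically predicted surface component (from the composition change)
and a lipid-specific residual; the two add back to the observation exactly,
by construction. For leaflet-symmetric comparisons
(`specific_shift_symmetric()`) the surface terms cancel and the whole shift
is read as specific. For vesicle-fusion experiments, where the deposited mole
fraction is not directly measurable, the default assumption is $x = 0.09$ —
the value calibrated from the ±20 mV shifts of POPG/POPS fusion — and it is
configurable.

The mole-fraction dose–response is fit as a rectangular hyperbola,
$V_{mid}(x) = V_0 + \Delta V_{max}\, x/(x + K_{1/2})$. The data are described
only as "approximately saturating", so the one-site form is a package design
choice; a Hill exponent can be fit as a third shape parameter
(`hill = TRUE`) and returns $h \approx 1$ on one-site data. Flat titrations
are flagged degenerate with $\Delta V_{max} = 0$ rather than fit.

```{r titration}
fit_saturation(c(0, 0.05, 0.1, 0.25, 0.5, 1),
               c(-71, -60, -43, -40, -33, -31))
```

$K_{1/2} < 0.1$: consistent with the effect being nearly complete by a mole
fraction of 0.1.

## The synthetic recording generator

`simulate_family()` produces sweep families with the statistical and
biophysical structure the analysis assumes, and records its generating truth
in a JSON sidecar for parameter-recovery tests. What it emulates:

- **Mixed orientations.** Channels insert in both orientations (default
  50/50). Inside-out channels respond to the negated command voltage with
  the leaflets swapped into the channel frame, so each orientation gets its
  own effective midpoint
  $V_{mid} = V_{mid}' + (\Phi_o - \Phi_i) + \Delta V_{max}\,x/(x+K_{1/2})$,
  the specific term evaluated on the channel-frame inner leaflet's
  primary-phosphate mole fraction.
- **Availability.** Inactivation appears only as a static,
  holding-voltage-dependent factor $a = 1/(1+e^{(v_{hold}-V_a)/s_a})$ — the
  minimal device that silences one orientation at a given holding voltage,
  which is the only role inactivation plays in this analysis. It is not a
  kinetic gate.
- **Kinetics.** The source data show activation time courses but state no
  rate law, so the generator adopts the minimal two-state form: exponential
  relaxation to the Boltzmann steady state with a bell-shaped
  $\tau(v) = \tau_0/\cosh(z_\tau(v - V_{mid})F/2RT)$ ($\tau_0 = 10$ ms
  default). Slowed activation in PA membranes is representable through
  $\tau_0$; the observed drop of $Z$ in PA (4.2 → 2.6) is treated as an
  independent input, since no mechanism links the two.
- **Current and noise.** Ohmic driving force with reversal 0 mV (symmetric
  K$^+$ after equilibration, no GHK permeation), population-mean open
  probability (no stochastic single-channel gating), additive white Gaussian
  noise with one deterministic substream per sweep derived from the seed —
  identical inputs and seed give bit-identical families.

What it deliberately does not emulate: capacitive transients, leak,
multi-state or C-type inactivation kinetics, bilayer instability, series
resistance. Passing tests therefore show that the analysis chain is correct
under its own model assumptions — not that real recordings satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Open probability uses the closed form per constant-voltage epoch; a
  property test checks end-of-step values against an independent
  explicit-Euler integration at a 1000×-finer step to $10^{-9}$ relative.
- Optimizer tolerances are set well below reporting precision
  (`ftol = 1e-15`, `ptol ≈ 1e-13`); noiseless round trips recover
  $(V_{mid}, Z)$ to better than $10^{-6}$.
- All-zero tail families, flat activation curves, flat titrations, unknown
  lipid species, non-physical mole fractions ($x > 1$) and malformed sweep
  files raise errors rather than propagate.
- Multiple half-max crossings are resolved by taking the first in protocol
  order.

**Problem sizes.** The validation suite runs desk-scale problems chosen to
make each property sharp rather than large: 20–26-sweep families at 0.5 ms
sampling, 8 replicate bilayers per condition for noisy-recovery checks (the
typical per-condition N of the experiments being emulated), 100 replicates
for the bias property, and titrations at the six published design points
with per-point V_mid averaged over 8 replicate bilayers (2 mV noise SD per
bilayer). Recovery tolerances (20% on dose–response parameters, 2 SEM on
means) were checked against the sampling distribution of the estimator at
these sizes before being frozen.

## Offset pass-through, forward/reverse equivalence

Two end-to-end invariants tie the modules together. Simulating with an
imposed leaflet asymmetry and fitting downstream recovers a $V_{mid}$ shift
equal to $\Phi_o - \Phi_i$ within 0.1 mV (noiseless); and in symmetric
membranes a forward protocol on outside-out channels and the mirrored
reverse protocol on inside-out channels give indistinguishable activation
curves. These checks use a −150 mV holding voltage so that both conditions
start from a fully closed state; from −110 mV, channels whose midpoint has
been shifted ~20 mV negative retain a few percent resting open probability,
which contaminates the tail baseline — visible in the simulator exactly as
it would be at the rig.

## Known limitations

- The Grahame treatment is monovalent and mean-field: no divalent screening,
  ion binding, or discreteness-of-charge corrections.
- PA is modeled as $-1$; if its second deprotonation is significant at
  pH 7.5 the surface component for PA-containing leaflets is underestimated
  and the residual specific component correspondingly overestimated.
- Decomposition ignores the concurrent change in $Z$; shifts are differences
  of fitted midpoints only.
- Vesicle-fusion surface components depend on an assumed deposited mole
  fraction (default 0.09, calibrated electrostatically, not measured).
- The mechanistic basis of the specific offset (arginine–phosphate
  interaction in the sensor) is outside the package's scope; the specific
  term is a phenomenological saturating function.
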