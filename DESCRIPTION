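Package: kvlipid
Title: Lipid Modulation of Voltage-Gated K+ Channel Activation in Planar Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how membrane lipid composition
    shifts the activation of voltage-gated K+ channels reconstituted into planar
    lipid bilayers. Extracts tail-current activation curves from voltage-clamp
    sweep families and fits the two-state Boltzmann equation to obtain the
    activation midpoint (V_mid) and apparent gating valence (Z); maps
    per-leaflet lipid compositions to surface charge densities and
    Gouy-Chapman/Grahame surface potentials; decomposes observed V_mid shifts
    into the electrostatically predicted surface-charge component and the
    residual lipid-specific component, including the saturating mole-fraction
    dose-response of phosphatidic acid; and simulates synthetic bilayer
    recordings (mixed channel orientations, holding-voltage-dependent
    availability, two-state kinetics, seeded Gaussian noise) so the whole
    pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
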