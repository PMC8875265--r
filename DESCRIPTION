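Package: adsorbkit
Title: Analysis Toolkit for Drug-Surface Adsorption Energetics, Dynamics and
    Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for quantum-mechanical studies of drug
    adsorption on oxide surfaces. Implements counterpoise (BSSE)
    interaction-energy decomposition into deformation, lateral and
    dispersion contributions; extended-XYZ molecular-dynamics trajectory
    analysis (RMSD time series, atom-pair distances with minimum-image
    convention, hydrogen-bond length histograms with Gaussian fits);
    proton-transfer event detection and transition-state-theory kinetics
    (Eyring barriers from observed rates); and broadened infrared spectra
    with gas-to-adsorbed band-shift matching. A seeded synthetic-data
    module generates two-state proton-transfer trajectories, energy ledgers
    with known decompositions, and mode tables, so the whole pipeline is
    testable without any electronic-structure code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
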