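Package: tspc4
Title: Thermal Stability Prediction of i-Motif DNA from Trajectory Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements MD-TSPC4, a pipeline that predicts the melting
    temperature (Tm) of intramolecular i-motif DNA from the conformational
    flexibility observed in molecular dynamics trajectories. Provides i-motif
    repeat-notation parsing with core/loop region assignment and C:C+ pair
    topology, region-aware trajectory statistics (best-fit RMSD, per-residue
    RMSF, radius of gyration, radial distribution functions, hydrogen-bond
    distance monitoring, loop-contact analysis), temperature-averaged RMSD
    summarisation with TR-plot linear calibration and Tm prediction, CD
    melting-curve Tm extraction by the first-derivative method, and seeded
    synthetic trajectory and melt-curve generators with closed-form ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
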