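Package: tmstarget
Title: Simulation and Analysis of TMS Functional Network Targeting on Cortical Surfaces
Version: 0.1.0
Authors@R:
    person("Taylor", "Reiter", email = "treiter@example.org", role = c("aut", "cre"))
Description: Tools to study which resting-state functional networks are
    engaged by transcranial magnetic stimulation (TMS) delivered over a grid
    of coil positions and orientations. Generates synthetic folded cortical
    patches with species-specific gyrification profiles and Yeo-7-style
    network parcellations, computes simplified figure-8 coil primary
    electric fields on the mesh, simulates resting-state fMRI with planted
    network covariance, extracts field-thresholded weighted seed regions,
    maps seed-to-cortex partial correlations with a shared covariate,
    sparsifies and assigns connectivity maps to networks, aggregates results
    over stimulation zones and coil-orientation windows, and computes the
    electric field stimulation index (EFSI). All stages also accept
    externally supplied meshes, label maps, field maps and time series in
    plain-text interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
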