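Package: sdocta
Title: Spectral-Domain OCT Angiography Processing and Flux-Artifact Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for spectral-domain optical coherence tomography
    angiography (OCT-A): an open raw interferogram format, k-space resampling,
    DC/autocorrelation mitigation, entropy-optimized dispersion compensation,
    Fourier reconstruction, BM-scan registration by translation and vertical
    shear, full-spectrum amplitude decorrelation angiography (FSADA) with
    structural masking and variable interscan time analysis, en-face slab
    projection over layer surfaces, and multi-scale Frangi vessel segmentation
    with density and Dice quantification. Includes a digital retina phantom
    (layered reflectivity, branching vessel trees, tunable blood-cell flux,
    injected dispersion and bulk motion) emulating euthermic and torpid
    perfusion regimes, an AOSLO-style video simulator with desinusoiding,
    frame registration and single-cell velocimetry, a square-wave blood-cell
    detectability model, and lateral image-scale calibration from scan
    geometry or point correspondences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
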