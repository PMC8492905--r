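Package: octafd
Title: Box-Counting Fractal Dimension of Macular OCTA Microvasculature
Version: 0.1.0
Authors@R: person("OCTA", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the complexity of the macular capillary network in
    en face optical coherence tomography angiography (OCTA) images. Provides
    classical vessel segmentation (multiscale Frangi vesselness with
    hysteresis thresholding), foveal avascular zone (FAZ) detection,
    construction of a FAZ-excluded parafoveal annulus (0.6-2.5 mm diameter),
    topology-preserving skeletonization, and the box-counting fractal
    dimension (D_box) of the skeletonized network. Includes cohort-level
    statistics for two-eyed study designs (generalized estimating equations
    with exchangeable working correlation and robust standard errors,
    correlation inference from summary statistics, LogMAR conversion,
    signal-quality filtering) and a synthetic-data module generating known
    fractals, vascular-tree-like angiograms with ground truth, and simulated
    cohorts with configurable group effects and inter-eye correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
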