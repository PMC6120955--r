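Package: DualScope
Title: Dual-Area Two-Photon Calcium Imaging Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-field two-photon calcium imaging of
    distant cortical areas acquired with a rotating post-objective mirror
    device. Provides closed-form calculators for the device geometry and
    acquisition timing, bead-based point-spread-function characterization
    (lateral and axial FWHM by Gaussian profile fits), per-trace processing
    of deconvolved spike events (percentile baselines, zero-phase Gaussian
    filtering, peak detection, frame-skip down-sampling, clock resampling,
    movement masking), somatic ROI selection by footprint shape, pairwise
    and distance-binned correlation analyses, soma-axon bouton functional
    matching, lever-pull behavioral metrics and trial selection, and the
    trial-to-trial population covariation analysis: movement-related
    classification, population vectors, affinity-propagation clustering of
    trials, cross-area intra-cluster correlation against a shuffle null,
    and inter-cluster distance agreement between areas. A synthetic-data
    module generates every input with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
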