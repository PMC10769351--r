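Package: presynQuant
Title: Quantification of Presynaptic Protein Localization from Confocal
    and STED Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the nanoscale localization of active-zone
    proteins (voltage-gated calcium channels and tagged rescue constructs)
    at synapses imaged by confocal and STED microscopy. Implements
    trans-synaptic line-profile extraction perpendicular to the PSD-95
    bar at side-view synapses, rolling-average smoothing and alignment of
    profiles to the PSD-95 peak, windowed peak-intensity extraction,
    Otsu-threshold segmentation of synapsin masks with area filtering,
    donut-shaped somatic ROI quantification, and the associated
    nonparametric and repeated-measures group statistics. A seeded
    synthetic-imaging module renders ground-truth synapse and soma fields
    (closed-form Gaussian-PSF rendering with Poisson and read noise) so
    that every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
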