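Package: modmap
Title: Modular Patch/Interpatch Analysis of Tangential Cortical Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the modular (patch/interpatch) organization of
    horizontal connections in tangential sections of mouse primary visual
    cortex. Delineates M2+ patches and M2- interpatches from fluorescence
    images by local-mean normalization, circular-average blurring and
    intensity-sextile partition; aligns serial sections to the layer-1
    reference frame with landmark-fitted projective transforms; and computes
    module-conditioned density statistics: per-quantile ROI optical density,
    radial density profiles around an injection center with core exclusion,
    point densities of cell bodies and apical dendrites, patch/interpatch
    preference ratios, moment-based anisotropy aspect ratios, and two-sample
    Kolmogorov-Smirnov comparisons. A synthetic-scene generator with planted
    ground truth (quasi-periodic module fields, distance-decaying anisotropic
    axon fields, inhomogeneous Poisson point sets, distorted serial stacks
    with shared landmarks) makes every stage testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
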