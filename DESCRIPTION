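Package: dosepaint
Title: PET Intensity-Based Dose Painting by Numbers: Planning and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for 18F-FDG-PET voxel intensity-based dose painting by
    numbers (DPBN) in radiotherapy. Generates fully synthetic three-phase
    head-and-neck phantom cases (CT surrogate, heterogeneous PET hotspots,
    structure sets, inter-phase deformation fields), maps PET intensity to a
    per-fraction dose prescription on randomly seeded points, builds and
    optimizes an intensity-modulated arc therapy (IMAT) class solution and a
    six-beam step-and-shoot IMRT comparator with a simplified photon dose
    engine, applies delivery post-processing (low-MU sub-arc pruning, control
    point refinement, sub-arc linking), accumulates multi-phase dose on the
    pretreatment grid through deformation fields, and evaluates plans with
    quality factors, DVH metrics, integral dose, detector-array sampling,
    3%/3mm global gamma analysis and paired Wilcoxon statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
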