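Package: npCTV
Title: Landmark-Based Clinical Target Volume Construction for
    Nasopharyngeal Cancer Radiotherapy
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based construction of radiotherapy clinical target
    volumes (CTV1, CTV2, CTV3, CTV4 and the composite CTV-Expansion and
    CTV-Overall envelopes) for nasopharyngeal cancer, from binary masks of
    head-and-neck anatomical structures, gross tumor volumes and TNM
    stage. Provides spacing-aware 3-D binary-mask morphology (exact
    Euclidean margin expansion, protected subtraction, opening/closing),
    landmark-driven axial polygon generation with Chaikin corner-cutting,
    nodal-level scenario logic for neck coverage, alpha-shape island
    joining, contour-comparison metrics (Dice similarity coefficient and
    mean surface distance), NIfTI mask input/output, and a seeded
    geometric head-and-neck phantom generator so the whole pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
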