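Package: BiopsySim
Title: Monte Carlo Simulation of Systematic and Image-Targeted Prostate
    Biopsy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates synthetic three-dimensional prostate and lesion
    models with the statistical structure of a whole-mount radical
    prostatectomy cohort, reconstructs gland models from 5-mm
    step-section contour stacks by shape-based interpolation with
    isotropic shrinkage correction, plans systematic 12-core
    transrectal-ultrasound and transperineal template-targeted biopsy
    schemes, simulates needle targeting error by Monte Carlo, and
    quantifies the resulting inflation of biopsy-derived risk
    parameters (maximum cancer core length, percentage of positive
    cores, risk classification, sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'cohort.R'
    'contours.R'
    'reconstruction.R'
    'geometry.R'
    'schemes.R'
    'simulate.R'
    'risk.R'
    'io.R'
    'pipeline.R'
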