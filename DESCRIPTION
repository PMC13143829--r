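Package: collmot
Title: Collective Cell Motility, Spheroid Wetting and Tissue-Microarray
    Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective cell motility in epithelial monolayers by
    windowed cross-correlation particle image velocimetry (PIV): total and
    drift-corrected root-mean-square velocities, the radial velocity-velocity
    correlation function with an exponential fit for the correlation length,
    and a flocking alignment index.  Companion modules quantify spheroid
    wetting (normalized spreading area and average front speed) and score
    multiplexed tissue-microarray cell tables into per-patient ECM (0-5) and
    YAP groups with Kaplan-Meier and log-rank survival comparison.  A seeded
    synthetic-data generator provides speckle movies advected by flows of
    known drift and correlation length, expanding-disk mask series, and
    cohort tables with known ground truth, so every stage is testable
    against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
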