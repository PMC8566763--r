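Package: vfgaze
Title: Detecting and Localizing Visual Field Defects from Free-Viewing Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for free-viewing eye-tracking studies of visual field
    defects (e.g. glaucoma). Reads eye-movement event tables and standard automated
    perimetry grids (Humphrey 24-2/30-2), computes basic fixation and saccade
    features, directional saccade-amplitude rank profiles against a control cohort,
    the viewing-priority statistic (gaze consistency scoring via fuzzy c-means),
    Gaussian visual-field maps with normalized-rank comparison, kernel PCA with
    naive-Bayes cross-validated group separation, and integrated-visual-field
    scoring. Includes a scotoma-conditioned scanpath simulator that generates
    control and patient cohorts with known ground truth for calibration and
    mechanism-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
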