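Package: tipm
Title: Analysis of Tilt-in-Place Calcium Imaging Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify neural responses to rapid body-tilt stimuli
    recorded with tilt-in-place microscopy (TIPM). Includes a forward
    simulator of stimulus kinematics, vestibular drive, and calcium-indicator
    fluorescence with per-cell ground truth; delta-F/F normalization under
    trial-baseline and anesthetized-baseline schemes; peak-response
    extraction, responsiveness testing, and trial variability; directional
    and magnitude tuning metrics (directionality index, roll-sensitivity
    slopes); a permutation-null classifier of longitudinal sensitivity change
    between two ages; and imaging/mounting quality control via normalized
    cross-correlation frame-shift estimation and landmark-based roll-angle
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
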