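Package: edhvol
Title: Automatic ABC/2 Volumetry for Traumatic Epidural Hematoma
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-slice geometric measurement on binary CT segmentation masks
    (area, maximum length, maximum perpendicular width), slice-weighted
    adjusted-depth computation, and the family of ABC/2 ellipsoid volume
    estimators for traumatic epidural hematoma, together with ordinary
    least squares calibration of new estimator variations against
    planimetry and a full accuracy-evaluation pipeline (percentage
    deviation, closest-value counts, deviation bins, Levene-gated t-tests,
    Bland-Altman limits of agreement). Includes synthetic phantom
    generators (ellipsoid, biconvex lens, irregular) with known true
    volumes, a packaged 53-case cohort table, minimal NIfTI-1 mask I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
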