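Package: owebp
Title: Oscillometric Blood Pressure Estimation with Variable Characteristic Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    cuff-deflation oscillometric recordings. Implements zero-phase band-pass
    detrending of the cuff-pressure signal, R-peak based pulse segmentation,
    rule-based rejection of movement-artifact pulses, cubic-spline fitting of
    the oscillometric waveform envelope, extraction of ten envelope features,
    and blood-pressure estimation by the fixed-ratio maximum amplitude
    algorithm or by variable characteristic ratios predicted with multiple
    linear regression or linear nu-support-vector regression. Includes a
    seedable simulator of cuff recordings with injectable movement artifacts,
    exhaustive and sequential floating feature selection under cross
    validation, and device-grading evaluation (Bland-Altman statistics, BHS
    cumulative-percentage grades, AAMI mean/SD criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
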