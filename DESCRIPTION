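Package: zebraheart
Title: Markerless Cardiac Physiology from Landmark-Tracked Zebrafish Ventricles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns markerless pose-estimation output (DeepLabCut-dialect tables of
    eight ventricle boundary landmarks) into a quantitative cardiac physiology
    panel for zebrafish embryos. Per-frame short- and long-axis lengths are
    converted to ventricular volume under a prolate-spheroid model; a
    prominence-based peak detector segments the volume trace into cardiac
    cycles, yielding heart rate, end-diastolic and end-systolic volume, stroke
    volume, cardiac output, ejection fraction and shortening fraction, plus
    Poincare-plot heart-rate-variability indices (sd1/sd2). A synthetic
    beating-heart simulator with full ground truth (tracking jitter, likelihood
    dropouts, slide drift, sudden-displacement events, inter-beat-interval
    jitter, and treatment-effect presets) supports validation without video.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
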