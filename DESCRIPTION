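Package: arksim
Title: Closed-Loop Autonomous Radial k-Space Sampling for Segmented Cine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for closed-loop
    ("autonomous") radial k-space view-angle selection in segmented cine
    cardiac MRI. Generates synthetic ECG with controllable rhythm, identifies
    prior periods of similar cardiac phase by normalized cross-correlation,
    selects each next radial view on-the-fly by bisecting the largest angular
    gap of the views collated into the current image frame, and compares the
    resulting trajectories against golden-angle, random and equispaced
    schedules using angular sampling uniformity statistics and point spread
    function main-lobe signal ratios. Includes an analytic dynamic ellipse
    phantom with adjoint gridding reconstruction for qualitative comparison
    of streak artifacts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
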