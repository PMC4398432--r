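Package: scenefam
Title: Scene-Familiarity Visual Navigation over Aerial Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for view-based route navigation over large
    grayscale aerial landscapes using the scene-familiarity principle: an
    agent retraces a learned route by moving toward the view most similar to
    its stored training views, with no map and no sequential recall. Provides
    a low-resolution downward-beam sensor model (histogram equalization,
    block-mean downsampling, gray-level quantization, circular field-of-view
    masking, view rotation), landscape information analytics (image-difference
    topography, familiarity volcano surfaces, rotational image difference
    functions, p50 catchment summaries), training-route construction with a
    rotated-view memory bank, an arc-scanning recapitulation agent, seeded
    synthetic landscape and route generators spanning three information
    regimes, and an experiment harness sweeping sensor resolution and pixel
    depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
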