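Package: hemitherm
Title: Differential Infrared Thermography of Facial Hemifaces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bilateral differential analysis of calibrated
    medical infrared thermograms. Extracts paired rectangular regions of
    interest from the healthy and diseased hemifaces, mirrors the healthy
    temperature matrix across the sagittal midline, subtracts it from the
    diseased matrix to obtain a pixel-wise thermal gradient map, zeroes
    values below a severity-dependent cut-off (2 degrees C for moderate,
    3 degrees C for severe inflammation), segments the surviving
    suprathreshold pixels into connected inflammation hotspots with shape
    descriptors, and repositions the main hotspot in full-frame
    coordinates for overlay display. Includes readers and writers for
    plain-text temperature grids with metadata sidecars and for 16-bit
    radiometric rasters with affine calibration, a synthetic facial
    thermal-phantom generator with ground-truth inflammation masks for
    validation, 3-D surface and overlay rendering, and a command-line
    interface for end-to-end case analysis and longitudinal session
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
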