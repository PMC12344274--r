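Package: satt
Title: Semi-Automatic Thresholding Tool for Flower Detection and
    Georeferencing in Oblique UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conspicuously coloured flowers (the motivating case is
    Himalayan balsam, Impatiens glandulifera, an invasive of riparian
    corridors) in oblique UAV photographs by HSV colour-space thresholding
    followed by Gaussian smoothing, elliptical-kernel morphological shape
    search, noise opening and contour extraction.  Detections are
    georeferenced monocularly from a known reference flower height through
    the pinhole camera model and spherical destination-point geometry, and
    exported as GIS vector layers (camera points, field-of-view footprint
    lines, flower-density points) in GeoJSON or ESRI Shapefile form.
    Includes detection-evaluation metrics (precision, recall, F1, 11-point
    interpolated average precision, mAP), a synthetic oblique-scene and
    riverbank-survey generator for end-to-end validation, and a command-line
    interface exposing the workflow as detect/tune/eval/georef/simulate
    subcommands.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    foreign,
    geosphere,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
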