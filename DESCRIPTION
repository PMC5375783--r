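Package: thermaseg
Title: Automatic Breast Thermogram Segmentation and Bilateral Asymmetry Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing frontal breast thermograms acquired with a
    radiometric infrared camera. Implements background removal by Otsu
    thresholding, fully automatic left/right breast segmentation from the
    inframammary fold (high-intensity threshold, distance-transform ranking,
    quadratic fold completion) and the armpit slope-change landmark,
    conversion of 8-bit grayscale thermograms to per-pixel temperature
    matrices in degrees Celsius, the 1 degree Celsius bilateral asymmetry
    screening rule, and watershed localization of the hottest region in the
    warmer breast. Includes a synthetic torso-phantom generator with ground
    truth for end-to-end validation, confusion-table screening metrics, and
    a file-based pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
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
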