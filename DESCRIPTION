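Package: hueseg
Title: Vegetation Segmentation of Crop-Field RGB Images by Hue-Histogram
    Threshold Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments vegetation from soil background in RGB images of
    agricultural fields. The core method converts an image to HSV, builds and
    filters the hue histogram, fits a two-term Gaussian model to it by
    Levenberg-Marquardt least squares, derives up to five candidate hue
    thresholds from the fitted curve and the filtered histogram (confidence
    interval of the dominant peak, inter-peak valley, and three local-minimum
    rules), and averages the admissible candidates into a single binarization
    threshold. Classical color-index baselines (NDI, ExG, ExR, ExGR, CIVE,
    COM1, COM2, NGRDI, VEG) with Otsu threshold detection, a pixel-accuracy
    evaluator, and a seeded synthetic field-image generator with exact ground
    truth are included for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
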