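Package: osmofret
Title: Ratiometric FRET Liposome Sensors for Osmotic Pressure Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for liposome-based ratiometric FRET osmotic
    pressure sensors. Provides unit conversions between NaCl mass fraction,
    molarity, osmolality and osmotic pressure (van't Hoff); a phenomenological
    forward model of the sensor FRET ratio versus external osmotic pressure,
    parameterized for a library of salt-loaded liposome formulations;
    emission-spectrum handling with background subtraction and the F562/F520
    peak ratio; monotone calibration-curve fitting (isotonic regression with
    shape-preserving interpolation), sensitivity and sensing-range estimation,
    and inversion of FRET ratio to pressure; and a confocal image-analysis
    chain with synthetic three-channel field generation, control-derived noise
    thresholds, segmentation, pixel-wise and ROI-sum FRET ratios, per-pixel
    pressure mapping, and time-lapse monitoring with change-point detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
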