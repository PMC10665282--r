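Package: spectcal
Title: Quantitative SPECT/CT Calibration with Solid Surrogate Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative SPECT/CT image calibration studies in
    which long-lived solid Ba-133 sources stand in for liquid I-131. The
    package simulates reconstructed count images of cylindrical sources
    mounted in a Jaszczak phantom with known ground truth, delineates
    volumes of interest (volume-matched thresholding, nominal geometry,
    enlarged masks), computes image calibration factors and pseudo image
    calibration factors in cps/MBq with a full uncertainty budget
    (Poisson counts, scan timing, radionuclide-calibrator components,
    rectangular weighing terms), combines dual-source measurements,
    fits setup-specific Ba-133 to I-131 cross-calibration lines and
    compares them with the gamma emission-probability ratio, and fits
    pseudo-recovery curves for partial-volume characterisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
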