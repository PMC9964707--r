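Package: nirsox
Title: Continuous-Wave NIRS Tissue Oximetry by the Modified Beer-Lambert Law
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of broadband diffuse-reflectance spectra from
    continuous-wave near-infrared spectroscopy of tissue surrounding bone
    implants. Implements the modified Beer-Lambert forward model, inversion
    of differential optical densities to oxy- and deoxyhemoglobin
    concentration changes and semi-quantitative tissue oxygen saturation
    using literature extinction coefficients and differential pathlength
    factors, principal-component exploration of longitudinal spectra with
    robust outlier flagging and score-space comparisons, and a synthetic
    study generator emulating a longitudinal rodent implant experiment
    (magnesium alloy, titanium, sham) with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
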