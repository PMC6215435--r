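Package: zfcardio
Title: Cardiovascular Phenotyping of Zebrafish Larvae from Calibrated
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of cardiovascular phenotypes in
    zebrafish embryos and larvae from calibrated microscopy: ventricular
    ellipse fitting and ellipsoid volumetrics from high-speed brightfield
    video (heart rate, stroke volume, cardiac output, shortening fraction,
    ejection fraction, fractional area change), erythrocyte-tracking
    velocimetry for venous and pulsatile arterial blood flow, pericardial
    edema area, three-dimensional vessel volume from confocal z-stacks,
    and a normality-gated two-group comparison layer. Includes synthetic
    image generators with exactly known ground truth for end-to-end
    validation of the full measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    mgcv,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
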