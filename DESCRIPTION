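Package: aortalab
Title: Axial-Stretch Bias in Cross-Sectional Aortic Distensibility Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-order quasi-static model of the proximal aorta for
    studying how neglecting systolic axial (longitudinal) stretch biases
    cross-sectional estimates of aortic distensibility. Implements the
    Holzapfel-Gasser-Ogden hyperelastic wall model with two dispersed
    collagen fiber families, thin-wall pressure-inflation equilibrium with
    elastic external tissue support, fixed-point restoration of the
    zero-pressure configuration, Bramwell-Hill pulse wave velocity
    calibration, a synthetic tapered curved-aorta generator with aortic-root
    motion scenarios, and the fixed-length versus variable-length conical
    integration estimators of volumetric distensibility, including a full
    sensitivity study over wall stiffness and root displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
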