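Package: ctstent
Title: Quantitative Image-Quality Analysis of Vascular Stents in CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how reconstruction-kernel sharpness affects
    the visualization of vascular stents in computed tomography.  Provides
    a digital stent-in-phantom simulator (contrast-filled silicone tube,
    metallic strut shell, kernel-dependent Gaussian blur and noise), the
    multi-row edge-rise-slope (ERS) profiling pipeline with 10-90 percent
    edge-rise-distance measurement, water-equivalent diameter (AAPM TG220),
    four-ROI coefficient-of-variation homogeneity analysis, and a reader
    study statistics layer (Friedman rank ANOVA, pairwise Wilcoxon with
    Bonferroni correction, Fleiss' kappa, repeated-measures ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
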