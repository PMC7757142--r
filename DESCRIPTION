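Package: fusbbb
Title: Focused-Ultrasound Blood-Brain Barrier Opening and Closure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing focused-ultrasound (FUS) induced blood-brain
    barrier (BBB) opening experiments with microbubbles. Implements the
    acoustic-emission feedback pressure controller (stepwise ramp, sub- and
    ultra-harmonic spectral detection, drop to a fraction of peak pressure,
    skull and tissue derating), quantification of gadolinium contrast
    enhancement in a 3x3-voxel region of interest with a two-standard-deviation
    closure classifier against the unenhanced hemisphere, focal-spot closure
    survival curves with log-rank (Mantel-Cox) comparisons under Bonferroni
    correction, Evans-blue semi-log standard-curve calibration, and the
    factorial group statistics (Type-III two-way ANOVA, Tukey-Kramer post-hoc,
    Grubbs outlier test). A synthetic-data module generates emission spectra,
    multi-timepoint enhancement images with programmed closure times,
    calibration standards and group designs so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    survival,
    car
Config/testthat/edition: 3
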