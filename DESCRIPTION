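Package: exomoment
Title: Moment-Arm Design and Lifting-Study Analysis for Passive Back-Assist Exosuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Static sagittal-plane modeling of the device-to-body forces and
    assistive torque produced by a routed-strap passive back-assist exosuit
    with an extended moment arm, together with the analysis pipeline of a
    lifting/lowering user study.  Computes shoulder, waist and thigh
    device-to-body forces, the assistive torque about L5-S1, the effective
    moment arm and the waist/shoulder force ratio K for any pulley placement;
    sweeps candidate moment-arm locations over a sagittal grid and ranks named
    configurations; generates complete synthetic studies (surface EMG,
    load-cell force channels, body-map discomfort reports); processes EMG
    (band-pass, sliding RMS, MVIC normalization) and force signals; and runs
    the study statistics (Shapiro-Wilk, Kruskal-Wallis, Mann-Whitney with
    Bonferroni correction, MANOVA with Tukey HSD follow-ups).
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
    signal,
    yaml,
    jsonlite,
    data.table
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
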