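Package: syrsed
Title: Particle Sedimentation in Horizontal Syringes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models, simulates and measures gravity-driven sedimentation of
    particles suspended inside a horizontal syringe, the sample reservoir of
    most microfluidic and lab-on-chip setups. Provides closed-form
    effective-concentration curves and concentration half-life bounds derived
    from Stokes terminal velocity and circle-intersection geometry, a
    Lagrangian particle-tracking simulator over semi-analytic or numerically
    solved creeping-flow fields in the barrel-plus-outlet geometry, a
    particle-counter signal-analysis chain (low-pass filtering, peak
    detection, event binning, throughput normalization, half-life
    extraction), and a synthetic detector-trace generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
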