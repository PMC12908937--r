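Package: frinstab
Title: Frictional Instability Classification and Tactile Discrimination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing stick-slip frictional instabilities in
    finger-surface sliding experiments and relating them to human tactile
    discrimination. Classifies tangential-force traces into steady sliding,
    slow frictional waves and stiction spikes using heuristic amplitude
    thresholds; builds instability phase maps over an applied-mass by
    driving-velocity grid and scores pairwise differential instability
    frequencies; computes surface descriptors (roughness, power-spectral
    Hurst exponent, contact-angle hysteresis) from AFM height maps and
    goniometer tables; and fits binomial and log-response-time mixed models
    linking instability differences to three-alternative forced-choice
    performance. Includes a spring-block contact-aging simulator and
    generators for self-affine height maps and behavioural trials so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    lme4,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
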