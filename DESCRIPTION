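Package: eitptx
Title: Synthetic Electrical Impedance Tomography Pipeline for Pneumothorax Detection
Version: 0.1.0
Authors@R:
    person("EIT", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis pipeline for pneumothorax (PTX)
    detection by thoracic electrical impedance tomography (EIT). Provides a
    two-dimensional pig-thorax conductivity phantom with pleural air lesions,
    tidal ventilation and cardiac spike dynamics; a 16-electrode adjacent-drive
    finite-difference forward model producing 208-measurement voltage frames;
    linearized time-difference image reconstruction with breath detection,
    tidal images, quadrant waveforms and per-pixel ventilation phase maps; a
    pooled-healthy-reference deviation-mapping PTX detection algorithm with
    anatomical segment localization; spike-potential waveform analysis with
    cardiac-frequency matching; and agreement / diagnostic-accuracy statistics
    (Cohen's kappa with interpretation bands, sensitivity, specificity,
    predictive values) together with an end-to-end synthetic study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
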