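Package: opmpipe
Title: Partial-Coverage OPM-MEG Sensorimotor Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of partial-coverage optically pumped
    magnetometer (OPM) magnetoencephalography recordings of sensorimotor
    responses to median nerve stimulation. Provides a conducting-sphere
    (Sarvas) forward model with lead fields and sensitivity maps, a
    synthetic multi-subject session generator planting somatosensory
    evoked fields (N20m/P35m/P60m) and mu/beta rhythm modulation
    (ERD/ERS), preprocessing with reference-array regression and
    homogeneous field correction (HFC), event-locked epoching, Morlet
    wavelet time-frequency analysis, regularized minimum-norm source
    estimation with ROI time-course extraction, and one-tailed paired
    JZS Bayes-factor statistics with N20m signal-to-noise summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
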