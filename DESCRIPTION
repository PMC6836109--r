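Package: acquisim
Title: In Silico Simulation of LC-MS/MS Fragmentation Strategies for
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scan-level simulator of liquid chromatography tandem mass
    spectrometry (LC-MS/MS) acquisition for untargeted metabolomics.
    Chemical objects are created either by sampling molecular formulae and
    empirical spectral features (m/z, retention time, intensity, scan
    durations, fragment peaks) from a database built from centroided mzML
    runs, or by converting regions of interest extracted from an existing
    run. A virtual mass spectrometer answers scan requests from pluggable
    controllers (full-scan MS1, Top-N data-dependent acquisition with
    dynamic exclusion, and a multi-sample data-set-dependent acquisition
    scheduler), advances a simulated clock with empirically sampled scan
    durations, and writes standards-conformant mzML. Fragmentation
    strategies are scored with a confusion-matrix evaluation of picked MS1
    features (precision, recall, F1) and multi-sample coverage counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
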