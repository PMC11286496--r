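Package: viscomarker
Title: Viscoelastic Creep Markers and Machine-Learning Classification of
    Liver Tissue States
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for diagnosing liver pathological states from the
    viscoelastic creep response of tissue measured by spherical AFM
    indentation.  Simulates cohorts of creep measurements from a double
    power-law (fractional) viscoelastic model, converts indentation records
    to creep compliance through the Hertz contact model, recovers nine
    viscoelastic markers (three elastic moduli, their sum, viscosity,
    relaxation time, transition frequency and two power-law exponents) by
    nonlinear least squares, and classifies healthy, drug-treated and
    fibrotic tissue with a soft-margin Gaussian-kernel support vector
    machine.  Includes marker ranking by SVM recursive feature elimination,
    cumulative Gaussian-noise feature ablation, cross-validated marker-count
    selection, and a drug-efficacy recovery report based on pairwise
    classification accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
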