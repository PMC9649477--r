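Package: blinkasym
Title: Blink-Reflex and MRI Asymmetry Indices for Early Parkinsonian
    Differential Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the early differential diagnosis of Parkinson's
    disease versus corticobasal syndrome from two lateralised biomarkers:
    the asymmetry index of the R2 blink-reflex recovery cycle (paired
    supraorbital stimulation EMG) and the asymmetry index of hemispheric
    cortical grey-matter metrics.  Includes extraction of R2 peak-to-peak
    amplitudes and recovery-cycle curves from raw EMG sweeps, asymmetry
    index computation with the contralateral hemisphere mapping, empirical
    ROC analysis with Youden optimal cutoffs, exact (Clopper-Pearson)
    binomial confidence intervals, binormal AUC, single- and combined-index
    classifiers fitted through dx_fit(), group-comparison statistics, a
    seeded synthetic-cohort and EMG-trace generator, and a reproducible
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
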