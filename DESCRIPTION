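Package: sagehr
Title: Seed-and-Guided Multi-Modal Topic Modelling for EHR Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Guided topic modelling of multi-modal electronic health record
    (EHR) data for high-throughput phenotyping. Diagnosis, medication and
    procedure codes are modelled as bags of words per patient; phenotype
    topics are anchored to PheCodes through seed-code distributions and a
    per-topic seed rate, patient-level topic priors are initialised by
    two-component Gaussian mixture fits to PheCode counts, and inference is
    collapsed variational Bayes (CVB0) with optional stochastic mini-batch
    updates. Fitted models yield calibrated continuous disease risk scores
    per patient and PheCode, exportable as PLINK-format quantitative traits,
    plus evaluation utilities (topic purity, phenotype similarity and
    comorbidity, precision-at-K incidence ranking) and a generative
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
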