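Package: clonefish
Title: Single-Cell Interphase-FISH Clonality Analysis for Hyperdiploid B-ALL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell sequential interphase-FISH
    copy-number data from high-hyperdiploid B-cell acute lymphoblastic
    leukemia. Encodes per-cell chromosome-gain profiles as subclone codes,
    parses a restricted ISCN karyotype dialect for concordance checks,
    calibrates binomial positivity cutoffs from diploid controls, computes
    clonal-heterogeneity statistics (Shannon entropy, percentage of major
    clone) and per-chromosome gain rates, infers the hierarchy of chromosome
    gains by complete-linkage clustering, builds and stress-tests a
    two-threshold trisomy-18/trisomy-10 relapse risk predictor, runs
    relapse-free-survival analyses (Kaplan-Meier, Cox, maximally selected
    rank cutpoints), classifies diagnosis-relapse clonal-evolution patterns,
    and simulates synthetic cohorts with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
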