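Package: memotrace
Title: Clinical NLP and Trajectory Analysis for Prodromal Dementia Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ontology-driven clinical natural language processing pipeline
    for extracting prodromal dementia entities (memory-loss symptoms, caregiver
    relations, cognition-enhancing medications, dementia diagnoses) from
    free-text outpatient notes, together with the downstream epidemiology:
    query expansion over skip-gram embeddings, a BiLSTM-CRF entity tagger with
    exact-span evaluation, rule-based relation linking, concept normalization,
    EHR cohort phenotyping, and regression models of the memory-complaint-to-
    diagnosis trajectory. A fully synthetic EHR generator with gold standoff
    annotations makes every stage testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
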