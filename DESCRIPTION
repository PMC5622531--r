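Package: litcomorbid
Title: Literature-Driven Comorbidity Burden Estimation from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven workflow for estimating the comorbidity burden of an
    index disease. Candidate comorbidities are selected by MeSH descriptor
    co-occurrence in the MEDLINE literature, restricted to a hierarchy subtree
    and ranked by citation counts; each comorbidity is expressed as machine
    usable detectors (ICD-10 code patterns with descendant and OR semantics,
    ATC drug-code prefixes, and text regular expressions); patients are
    phenotyped from coded diagnoses, prescriptions and free-text documents,
    with optional two-reviewer adjudication of text candidates; prevalence is
    estimated with Wald or Wilson score intervals, agreement with Cohen's
    kappa, encounter regularity with Sperrin's I, and literature concordance
    with tie-aware Spearman correlation. A synthetic electronic-health-record
    generator with configurable prevalence, per-source detection sensitivity
    and encounter-timing regularity makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
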