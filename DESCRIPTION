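Package: csftdna
Title: Quantification and Monitoring of Cerebrospinal-Fluid Tumor DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-informed quantification of cell-free tumor DNA in
    cerebrospinal fluid (CSF) and plasma from deep targeted sequencing
    count tables. Estimates position-specific background error from
    control samples, performs tumor-naive variant calling with germline
    and coding filters, builds patient-level joint reporter sets, and
    quantifies tumor DNA per sample by mean variant allele fraction
    together with an empirical Monte Carlo detection index (detection
    declared at index <= 0.05). Calls gene-level focal copy-number
    changes by z-score against a background cohort, identifies emergent
    resistance alterations after targeted therapy and compares them
    across plasma and CSF, classifies leptomeningeal disease (LMD)
    status, and runs the diagnostic-sensitivity, survival, correlation
    and drug-penetration analyses used in CSF liquid-biopsy studies. A
    synthetic cohort generator with known ground truth makes every stage
    testable end to end.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
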