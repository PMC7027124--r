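Package: germscan
Title: Pan-Cancer Prognostic Germline Variant Discovery and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of germline variants associated
    with cancer patient outcome. Merges genotype calls from normal-exome,
    tumor-exome, and tumor-RNA sequencing with depth masking and concordance
    quality control; scans variants for survival associations with Cox
    proportional-hazards models (per cancer and in pooled cancer groups with
    interaction designs), using Lasso-selected clinical covariates and
    Benjamini-Hochberg false discovery control; characterizes hits
    (direction concordance, hazard-ratio correlations, minor-allele
    enrichment, genomic region, linkage pruning, variant-pair independence,
    somatic driver-mutation association); evaluates added predictive value
    with time-dependent ROC curves under inverse-probability-of-censoring
    weighting; triages candidate cis expression quantitative trait loci; and
    performs survival power analysis. Includes a synthetic-cohort generator
    with planted effects so the full pipeline is testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
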