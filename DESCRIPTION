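Package: pclexome
Title: Somatic Mutation Analysis for Plasma Cell Leukemia Whole-Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a whole-exome somatic-mutation
    analysis workflow for small tumor cohorts with incomplete matched-normal
    coverage, modeled on primary plasma cell leukemia. Provides a germline
    filter cascade that works in paired and unpaired (pooled-normal) modes
    with sub-clonal labeling and a germline carry-over audit; trinucleotide
    mutational-signature spectra with non-negative least-squares attribution
    to aging- and APOBEC-like processes; integration of copy-number segments
    with mutations to call biallelic (two-hit) tumor-suppressor inactivation;
    gene-recurrence and pathway damaging-variant enrichment with Fisher and
    resampling nulls; expression-side clustering, cluster-replication and
    differential-expression analyses; and a synthetic-cohort generator with a
    full ground-truth channel so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    pracma,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
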