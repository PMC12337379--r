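Package: uromethylome
Title: Genome-Wide Urinary DNA Methylation Analysis for Bladder Cancer
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-methylation analysis of urinary cell-pellet DNA
    from nanopore 5mC pileups (bedMethyl). Provides a two-state hidden
    Markov model that segments spatially correlated methylation
    differences between a cancer and a control group, a filtering and
    Mann-Whitney triage cascade that yields a high-confidence set of
    differentially methylated regions (DMRs), label-permutation and
    random-segment null models, genomic-context and repeat-content
    annotation, delta-ranked gene-set enrichment analysis, shallow
    whole-genome copy-number burden estimation, and cohort discrimination
    via PCA, hierarchical clustering and cross-sample correlation. A
    synthetic urinary-methylome generator with a ground-truth ledger
    (planted promoter hypermethylation, intergenic hypomethylation,
    tumour-fraction dilution, depth tiers, arm-level copy-number events
    and pathway structure) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
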