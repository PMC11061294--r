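Package: ct5hmc
Title: Cell-Type-Aware Analysis of 5mC and 5hmC from Paired BS/oxBS Arrays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-type-aware epigenome-wide analysis of DNA
    methylation (5mC) and hydroxymethylation (5hmC) in bulk tissue measured
    with paired bisulfite (BS) and oxidative-bisulfite (oxBS) arrays.
    Provides constrained maximum-likelihood inference of 5mC/5hmC from
    paired beta values, a per-sample methylation dysregulation index (MDI)
    against a non-tumor reference, covariate-adjusted epigenome-wide
    association models with empirical-Bayes variance moderation and stepwise
    cell-composition adjustment, cell-type interaction models attributing
    differential modification to neuronal-like or progenitor-like cells,
    Mantel-Haenszel genomic-context enrichment stratified by Infinium probe
    design type, negative-binomial differential expression with composition
    covariates, binned-control gene-set expression scores, single-nucleus QC
    and hashtag/genotype demultiplex consolidation, and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2
Config/testthat/edition: 3
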