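Package: pathrha
Title: Pathway Association, Regional Heritability and Polygenic Risk
    Profiling for Case/Control Traits
Version: 0.1.0
Authors@R:
    person("pathrha", "developers", email = "pathrha@example.org",
           role = c("aut", "cre"))
Description: A two-stage analysis pipeline for complex binary traits:
    stage-1 pathway association from either raw genotypes (gene eigenSNP
    ridge regression with phenotype permutation) or GWAS summary statistics
    (95th-percentile gene-score enrichment), followed by stage-2 multilevel
    regional heritability analysis (pathway, gene and sliding-window block
    level) using average-information REML with genomic relationship
    matrices, boundary-corrected likelihood-ratio tests and circular
    genomic permutation nulls.  Includes polygenic risk profiling
    (clumping and p-value thresholding, Nagelkerke R2, Mann-Whitney AUC,
    and a PRS-bin-relationship-matrix random-effect model) and a
    synthetic-cohort generator (LD-blocked genotypes, liability-threshold
    phenotypes with pathway-enriched heritability, ascertained
    case/control sampling, independent discovery summary statistics) so
    the whole pipeline is testable without external data.  Reads and
    writes PLINK-1 bed/bim/fam, GMT gene sets, GCTA-format GRMs and TSV
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
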