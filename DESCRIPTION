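Package: grextas
Title: Transcriptome-Wide Association Testing with Genetically Regulated
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for transcriptome-wide association studies
    (TWAS) of case-control traits. Trains per-gene cis elastic-net models of
    gene expression on a reference panel, writes and reads a PredictDB-style
    weight database, imputes genetically regulated expression (GReX) into
    genotyped cohorts after quality-control filtering and allele
    harmonization, tests per-gene association with disease by covariate-
    adjusted logistic regression with false-discovery-rate control and
    genomic-inflation diagnostics, combines replication cohorts by
    fixed-effect inverse-variance meta-analysis under a Bonferroni
    replication rule, and refines known GWAS risk loci by interval merging
    and transcription-start-site intersection. Includes a synthetic-data
    generator with known ground truth (LD-structured dosages, sparse
    cis-eQTL architecture with tunable heritability, a logistic disease
    model) so that every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
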