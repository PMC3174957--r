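Package: eqtlpipe
Title: Integrative cis-eQTL Mapping and eQTL-Informed GWAS Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage integrative genomics pipeline for case-only
    expression cohorts: covariate-adjusted cis-eQTL scanning with
    Benjamini-Hochberg false discovery rate control, disease association
    of the significant eQTL SNPs under a reduced (Bonferroni) multiple
    testing burden, pooled mega-analysis and fixed-effects inverse-variance
    meta-analysis across case-control studies, a sequential two-cohort
    replication screen with effect-direction consistency, and tag-SNP
    linkage-disequilibrium bin dissection of candidate loci. Includes a
    haplotype-block synthetic-data generator with planted cis and disease
    effects so every stage is testable without external data, plus readers
    and writers for VCF and the pipeline's TSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
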