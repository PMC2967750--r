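Package: phapscore
Title: Knowledge-Filtered Gene-Level SNP Aggregation Scores for Pharmacogenomic GWAS
Version: 0.1.0
Authors@R: person("phapscore", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Gene-level aggregation of SNP genotypes into per-patient pHap
    scores (sums of negative log genotype frequencies) for small
    pharmacogenomic cohorts. Provides genotype input from VCF or dosage
    tables, linkage-disequilibrium pruning by pairwise r-squared, windowed
    SNP-to-gene mapping with manual overrides, univariate regression and
    two-sample t-test screens with Bonferroni correction, extreme-dose
    dichotomization, cross-validated logistic classification with ROC/AUROC
    and random-gene-set empirical significance, plus a synthetic-cohort
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
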