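Package: mutsigscan
Title: Case-Only Association Between Germline Variants and Somatic
    Mutation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-only candidate-gene association studies that
    relate inherited germline variants to somatic mutation "signatures"
    in tumors, modelled on gastrointestinal stromal tumors (GIST) driven
    by KIT or PDGFRA mutations.  Provides a sample- and variant-level
    quality-control cascade, a seven-category somatic mutation
    classifier, covariate-adjusted per-allele logistic screening with
    Benjamini-Hochberg false discovery rate control, and a gene-level
    logistic kernel-machine variance-component score test (SKAT) with an
    identity-by-state kernel, moment-matched and exact mixture
    chi-squared p-values, and a permutation oracle.  A synthetic cohort
    generator with stratified Hardy-Weinberg genotypes, within-gene
    linkage disequilibrium and planted per-allele effects makes every
    stage testable without individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
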