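Package: resiphy
Type: Package
Title: Residual-Disease Phylogenomics with Purity-Aware Absence Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-region tumour phylogenomics for residual disease.
    Selects putative truncal somatic SNVs from high-purity tumour-mass
    samples using purity- and copy-number-corrected cancer cell fractions,
    fits per-copy-number-state beta-binomial models of truncal variant
    allele frequency, and tests whether truncal SNVs undetected in
    low-purity infiltrative-margin or sub-ventricular-zone samples are
    truly absent rather than sequencing false negatives, at a conservative
    worst-case purity with Bonferroni correction. Builds rooted
    maximum-parsimony sample phylogenies (germline outgroup, exact
    branch-and-bound search, Fitch mutation assignment, bootstrap support)
    after excluding mutations whose margin status the test leaves
    undetermined. Includes a seeded clonal-evolution read-count simulator
    emulating a multi-region glioblastoma sampling design, so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
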