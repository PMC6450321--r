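Package: caseonly
Title: Case-Only Rare-Variant Discovery and Characterization in
    Case-Control Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterizing rare coding variants
    observed only in cases of a case-control sequencing study, as applied
    to dementia cohorts. Implements impact-aware case-only carrier
    filtering, EM haplotype-frequency estimation in windows around a focal
    rare variant with shared-haplotype detection among carriers, pairwise
    linkage disequilibrium, method-of-moments identity-by-descent
    estimation, ancestry principal components with subcluster
    carrier-enrichment testing, collapsed (CMC) rare-variant burden
    regression with a Firth fallback, hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, and
    affected-relative sharing filters for pedigree data. Includes a
    synthetic cohort generator with population substructure, cryptic
    relatedness, haplotype backgrounds, and planted case-only variants
    providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
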