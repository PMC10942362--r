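Package: rvburden
Title: Rare-Variant Burden and Trend Testing for Case-Control Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control rare-variant association analysis for targeted
    sequencing panels: a variant- and sample-level quality-control cascade
    (GATK-style hard filters, Hardy-Weinberg exact test, pairwise
    relatedness, ultra-rare-variant balance checks), a one-sided Fisher
    single-variant scan with permutation-based FDR and genomic-inflation
    diagnostics, gene-level collapsing tests (CMC carrier collapsing,
    a SKAT-O style combined burden/variance-component test, CAST), the
    variable-threshold Cochran-Armitage rare-variant trend test (RVTT)
    with permutation p-values, Cauchy combination meta-analysis across
    cohorts, and permutation/hypergeometric gene-set enrichment. Includes
    a synthetic-cohort generator that emulates the statistical structure
    of a targeted case-control panel so every stage is testable without
    access-restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
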