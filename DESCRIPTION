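Package: popnovel
Title: SNV Quality Control, Novelty Assessment and Ancestry Projection for
    Small Whole-Genome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of multi-sample whole-genome SNV calls at
    small cohort scale. Sites are classified against truth panels and
    filtered by compound site-metric rules scored with a discrimination
    factor, then recalibrated with a Gaussian-mixture log-odds score
    (a VQSLOD-style statistic). Surviving alleles are normalized (multiallelic
    splitting, indel left-alignment), compared with reference variant panels
    to find novel alleles, functionally characterised against transcript
    models with fixed precedence ladders, and summarised as allele-count
    spectra and per-chromosome block densities. Ancestry of query samples is
    inferred by projecting genotypes onto a principal-component model fitted
    to a reference population panel after minor-allele-frequency, proximity,
    accessibility-mask, Hardy-Weinberg and variance-inflation-factor LD
    filtering. A synthetic-data generator produces every input with known
    ground truth, including Balding-Nichols admixed genotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
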