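Package: raredx
Title: Rare-Disease Variant Prioritization from Family Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causative variants for rare Mendelian
    diseases from multi-sample VCF genotypes and pedigrees. Implements
    inheritance-mode segregation filters (dominant, recessive homozygous,
    compound heterozygous, X-linked, de novo) with cross-family control
    exclusion, 1000 Genomes multi-population frequency and database
    filters, an in silico predictor consensus vote, a
    misclassification-tolerant affection-label relabeling search, a
    chromosome- and window-level variant-density enrichment scan that
    localizes hidden repeat-expansion loci from co-segregating linkage
    blocks, and de novo copy-number segment detection by reciprocal
    overlap. Ships a seeded synthetic family-cohort generator with a
    machine-readable truth manifest for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
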