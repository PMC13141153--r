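Package: haplocall
Title: Haplotype-Aware Two-Pass Small-Variant Calling for Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of an accelerated
    haplotype-aware two-pass small-variant calling workflow for long-read
    sequencing data. A fast pileup pass nominates candidate sites and calls
    easy variants; high-quality heterozygous SNPs are phased with a two-stage
    greedy graph algorithm; reads are haplotagged in memory from the phased
    haplotypes; and low-confidence sites are refined by a haplotype-sorted
    full-alignment pass with a multi-task genotype decision. Includes genome
    chunking for parallel work units, pluggable classifier backends with a
    fixture trainer, VCF/GVCF output, a precision/recall/F1 evaluator over
    five variant categories, and a seeded diploid long-read simulator so the
    whole pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    nnet,
    parallel,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
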