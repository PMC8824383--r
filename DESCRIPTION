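Package: sexrec
Title: Sex Chromosome Discovery and Sex-Specific Recombination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying nascent sex chromosomes and characterising
    heterochiasmy from pooled sequencing, pedigree and expression data. Implements
    pooled-DNA delta-allele-frequency genome scans with Z-score window flagging,
    sex-linked SNP extraction, expression-based genetic sexing by hierarchical
    clustering of expressed allele ratios, a two-group differential expression
    screen, allelic-imbalance calling, crossover detection from phased pedigrees
    with sex-specific genetic maps and classification of chromosomes into male-only
    and female-only recombination regions, windowed nucleotide diversity from
    pileup-like site tables, repeat-class density contrasts from RepeatMasker
    annotation, molecular dating of a non-recombining Y stratum, and detection of
    LTR retrotransposon boundaries and target-site duplications. A seeded synthetic
    data generator reproduces the statistical structure these analyses assume and
    emits a machine-readable truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
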