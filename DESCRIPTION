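Package: phenoseqr
Title: Pathway-Based Phenotype Sequencing of Pooled Mutant Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the genes and pathways that cause a screened
    phenotype from pooled sequencing of independently mutagenized
    microbial strains.  Variant calls are filtered (quality, strand
    bias, pool allele frequency, parental sites), mapped onto CDS
    features of an annotated reference genome and classified as
    synonymous or nonsynonymous.  Genes and gene groups (pathways) are
    then scored with a Poisson mutational-target model whose expected
    cross-section derives from the unit's GC/AT composition and
    genome-wide per-site mutation densities, with companion
    positive-selection (one-tailed Fisher exact on Ka/Ks-like counts),
    hypergeometric enrichment and causal-mutation-count estimators, a
    Wright-Fisher diversity-loss simulator for experiment design, and a
    forward generator of synthetic mutagenesis experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
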