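Package: vectann
Title: Vectorized Privacy-Preserving Variant Annotation and Genotype Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a vectorized framework for outsourcing variant
    annotation and allele-frequency aggregation to an untrusted server
    without revealing variant loci or genotypes. Extended coding regions
    are stitched into a linear coordinate system; every possible point
    mutation (four SNV alleles, 1-bp deletion, 1-bp insertion) is
    pre-annotated into 58-bit packed impact vectors; client variants are
    encoded as binary loci vectors and annotated by slot-wise
    multiplication under a SIMD-style encryption contract. Deletions and
    insertions of arbitrary length are translated from the 1-bp impact
    signals by merging coding-frame, neighborhood and junction-codon
    information. Genotype matrices from multiple sources are pooled via
    key switching and aggregated into exact allele counts, including an
    exact-span deletion-length statistic. A bit-exact plaintext mock
    backend makes the whole protocol testable without cryptographic
    dependencies, and a synthetic-data module generates genomes, gene
    models, variants and genotypes in standard formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
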