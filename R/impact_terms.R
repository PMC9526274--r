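#' The canonical 38-term consequence vocabulary
#'
#' Variant consequences are encoded as a 38-bit bitmap, one frozen index per
#' term. Indices 0-19 follow the coding-region consequence table order
#' (intron through splice acceptor); the remaining indices complete the
#' standard consequence vocabulary in alphabetical order so that bitmaps are
#' interoperable public constants. Each term carries the standard 4-level
#' severity class. The six terms conventionally treated as HIGH impact for
#' coding genes are `frameshift_variant`, `splice_acceptor_variant`,
#' `splice_donor_variant`, `stop_gained`, `stop_lost` and `start_lost`
#' (see [high_impact_terms()]).
#'
#' @return a tibble with columns `index` (0-based, frozen), `term`,
#'   `severity` (HIGH/MODERATE/LOW/MODIFIER).
#' @examples
#' impact_terms()
#' @export
impact_terms <- function() {
  tibble::tibble(
    index = seq_along(.term_list) - 1L,
    term = .term_list,
    severity = unname(.term_severity[.term_list])
  )
}

.term_list <- c(
  # coding-region table order (frozen)
  "intron_variant", "3_prime_UTR_variant", "5_prime_UTR_variant",
  "coding_sequence_variant", "synonymous_variant", "stop_retained_variant",
  "start_retained_variant", "incomplete_terminal_codon_variant",
  "splice_region_variant", "protein_altering_variant", "missense_variant",
  "inframe_deletion", "inframe_insertion", "transcript_amplification",
  "start_lost", "stop_lost", "frameshift_variant", "stop_gained",
  "splice_donor_variant", "splice_acceptor_variant",
  # remaining standard vocabulary, alphabetical
  "downstream_gene_variant", "feature_elongation", "feature_truncation",
  "intergenic_variant", "mature_miRNA_variant", "NMD_transcript_variant",
  "non_coding_transcript_exon_variant", "non_coding_transcript_variant",
  "regulatory_region_ablation", "regulatory_region_amplification",
  "regulatory_region_variant", "splice_donor_5th_base_variant",
  "splice_polypyrimidine_tract_variant", "TF_binding_site_variant",
  "TFBS_ablation", "TFBS_amplification", "transcript_ablation",
  "upstream_gene_variant"
)

.term_severity <- c(
  intron_variant = "MODIFIER", `3_prime_UTR_variant` = "MODIFIER",
  `5_prime_UTR_variant` = "MODIFIER", coding_sequence_variant = "MODIFIER",
  synonymous_variant = "LOW", stop_retained_variant = "LOW",
  start_retained_variant = "LOW", incomplete_terminal_codon_variant = "LOW",
  splice_region_variant = "LOW", protein_altering_variant = "MODERATE",
  missense_variant = "MODERATE", inframe_deletion = "MODERATE",
  inframe_insertion = "MODERATE", transcript_amplification = "HIGH",
  start_lost = "HIGH", stop_lost = "HIGH", frameshift_variant = "HIGH",
  stop_gained = "HIGH", splice_donor_variant = "HIGH",
  splice_acceptor_variant = "HIGH",
  downstream_gene_variant = "MODIFIER", feature_elongation = "MODIFIER",
  feature_truncation = "MODIFIER", intergenic_variant = "MODIFIER",
  mature_miRNA_variant = "MODIFIER", NMD_transcript_variant = "MODIFIER",
  non_coding_transcript_exon_variant = "MODIFIER",
  non_coding_transcript_variant = "MODIFIER",
  regulatory_region_ablation = "MODERATE",
  regulatory_region_amplification = "MODIFIER",
  regulatory_region_variant = "MODIFIER",
  splice_donor_5th_base_variant = "LOW",
  splice_polypyrimidine_tract_variant = "LOW",
  TF_binding_site_variant = "MODIFIER", TFBS_ablation = "MODIFIER",
  TFBS_amplification = "MODIFIER", transcript_ablation = "HIGH",
  upstream_gene_variant = "MODIFIER"
)

#' The six HIGH-impact coding-region terms
#'
#' @return character vector of the six consequence terms treated as HIGH
#'   impact on coding genes.
#' @export
high_impact_terms <- function() {
  c("frameshift_variant", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "stop_lost", "start_lost")
}

#' Write the canonical term index table as TSV
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_impact_terms <- function(path) {
  readr::write_tsv(impact_terms(), path)
  invisible(path)
}

term_index <- function(terms) {
  idx <- match(terms, .term_list)
  if (anyNA(idx)) {
    stop("unknown consequence term(s): ",
         paste(terms[is.na(idx)], collapse = ", "))
  }
  idx - 1L
}

#' Convert between term sets and 38-bit bitmaps
#'
#' A bitmap is a double below 2^38 (exactly representable) with bit *i* set
#' when the term of index *i* applies.
#'
#' @param terms character vector of consequence terms.
#' @param bitmap a bitmap value (double, < 2^38).
#' @return `terms_to_bitmap()` a bitmap; `bitmap_to_terms()` a character
#'   vector of terms in canonical index order.
#' @examples
#' bitmap_to_terms(terms_to_bitmap(c("missense_variant", "intron_variant")))
#' @export
terms_to_bitmap <- function(terms) {
  if (length(terms) == 0) return(0)
  sum(2^unique(term_index(terms)))
}

#' @rdname terms_to_bitmap
#' @export
bitmap_to_terms <- function(bitmap) {
  stopifnot(length(bitmap) == 1, bitmap >= 0, bitmap < 2^38)
  .term_list[bitmap_bits(bitmap)]
}

# 1-based indices of set bits in a < 2^38 double bitmap
bitmap_bits <- function(bitmap) {
  which(floor(bitmap / 2^(0:37)) %% 2 == 1)
}

bitmap_has <- function(bitmap, term) {
  i <- term_index(term)
  floor(bitmap / 2^i) %% 2 == 1
}
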