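#' Length-specific deletion annotation vectors
#'
#' The alternative to 1-bp merge translation: one annotation vector per
#' deletion length, where the entry at vector position `nu` packs the full
#' consequence of deleting the `del_len` bases starting at `nu`'s genomic
#' position from the region's element. Exact by construction — the
#' consequence is computed by the direct annotator, junction codons on the
#' true spliced sequence included — at the cost of one vector (and one
#' encrypted loci vector) per length. Supported for `del_len` up to 20.
#'
#' @inheritParams build_annotation_vectors
#' @param del_len deletion length in bases (1 to 20).
#' @return an `annotation_vector` whose `allele` is `"d<len>"`.
#' @seealso [translate_deletion_length()] for the client-side decode,
#'   [translate_deletion()] for the single-vector merge path.
#' @export
build_deletion_length_vector <- function(model, store, targets, del_len) {
  stopifnot(del_len >= 1, del_len <= 20)
  g <- vector_to_genomic(targets, seq_len(targets$l_T))
  dels <- dplyr::distinct(
    tibble::tibble(chrom = g$chrom, d1 = g$pos,
                   d2 = g$pos + as.integer(del_len) - 1L))
  rec <- annotate_variants_direct(model, store, targets,
                                  variant_set(deletions = dels))
  key <- paste(rec$chrom, rec$start, rec$element_id)
  bitmaps <- stats::setNames(
    vapply(rec$terms, terms_to_bitmap, numeric(1)), key)
  want <- paste(g$chrom, g$pos, g$element_id)
  bm <- unname(bitmaps[want])
  bm[is.na(bm)] <- 0

  # frame and neighborhood of the first deleted base, as in the 1-bp vector
  frames <- integer(targets$l_T)
  nbs <- character(targets$l_T)
  for (tx in unique(targets$regions$source_tx)) {
    ctx <- transcript_context(model, store, tx)
    idx <- which(targets$regions$source_tx[g$region] == tx)
    cl <- classify_positions(ctx, g$pos[idx])
    frames[idx] <- cl$pos_in_codon
    nbs[idx] <- neighborhood_of(ctx$chromseq, g$pos[idx], "d")
  }
  packed <- unclass(pack_impact(frames, encode_neighborhood(nbs), bm))
  packed[bm == 0] <- 0
  class(packed) <- "i64"
  structure(list(allele = paste0("d", del_len), values = packed,
                 l_T = targets$l_T, target_hash = target_hash(targets)),
            class = "annotation_vector")
}

#' Encode deletions of one exact length as a start-position loci vector
#'
#' @param vs a `variant_set`.
#' @param targets a `target_set`.
#' @param del_len the deletion length this vector carries.
#' @return a `loci_vector` with a bit at each matching deletion's start.
#' @export
vectorize_deletion_starts <- function(vs, targets, del_len) {
  d <- vs$deletions[vs$deletions$d2 - vs$deletions$d1 + 1 == del_len, ]
  bits <- integer(targets$l_T)
  n_hit <- 0L
  if (nrow(d) > 0) {
    m <- genomic_to_vector(targets, d$chrom, d$d1)
    bits[m$nu] <- 1L
    n_hit <- length(unique(paste(m$chrom, m$pos)))
  }
  structure(
    list(allele = paste0("d", del_len), bits = bits, l_T = targets$l_T,
         target_hash = target_hash(targets),
         n_variants = nrow(d), n_off_target = nrow(d) - n_hit),
    class = "loci_vector"
  )
}

#' Translate a decrypted length-specific deletion vector
#'
#' No merging needed: each non-zero slot already packs the full consequence
#' of the `del_len`-base deletion starting there.
#'
#' @param decrypted `i64` vector of length `l_T`.
#' @param targets the `target_set`.
#' @param del_len the deletion length of the vector.
#' @return an annotation-record tibble.
#' @export
translate_deletion_length <- function(decrypted, targets, del_len) {
  stopifnot(length(decrypted) == targets$l_T)
  nz <- i64_nonzero(decrypted)
  if (length(nz) == 0) return(empty_records())
  g <- vector_to_genomic(targets, nz)
  u <- unpack_impact(decrypted[nz])
  acc <- rec_acc()
  for (j in seq_along(nz)) {
    acc$add(g$chrom[j], g$pos[j], g$pos[j] + as.integer(del_len) - 1L,
            "del", NA_character_, g$element_id[j],
            bitmap_to_terms(u$bitmap[j]))
  }
  acc$build() |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$type,
                    .data$element_id, .keep_all = TRUE)
}

#' Import externally produced point-mutation annotations
#'
#' Lets an external annotator replace the built-in one bit-for-bit: a
#' tab-delimited table with columns `chrom`, `pos`, `allele` (one of
#' [point_alleles()]), `element_id`, `terms` (comma-separated consequence
#' terms from [impact_terms()]) and `frame` is packed into an
#' `annotation_vector`; neighborhoods are extracted from the genome
#' sequence. Positions/elements absent from the table stay 0.
#'
#' @param path the TSV file.
#' @param targets a `target_set`.
#' @param store a `seq_store` (for the 6-bp neighborhoods).
#' @param allele which allele's vector to build.
#' @return an `annotation_vector`.
#' @export
read_annotation_tsv <- function(path, targets, store, allele) {
  stopifnot(allele %in% point_alleles())
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", allele = "c", element_id = "c",
    terms = "c", frame = "i"))
  tab <- tab[tab$allele == allele, ]
  g <- vector_to_genomic(targets, seq_len(targets$l_T))
  key <- paste(tab$chrom, tab$pos, tab$element_id)
  hit <- match(paste(g$chrom, g$pos, g$element_id), key)
  bm <- numeric(targets$l_T)
  fr <- integer(targets$l_T)
  ok <- !is.na(hit)
  bm[ok] <- vapply(strsplit(tab$terms[hit[ok]], ",", fixed = TRUE),
                   terms_to_bitmap, numeric(1))
  fr[ok] <- tab$frame[hit[ok]]
  nb <- vapply(seq_len(targets$l_T), function(i) {
    neighborhood_of(store$seq[[g$chrom[i]]], g$pos[i], allele)
  }, character(1))
  packed <- unclass(pack_impact(fr, encode_neighborhood(nb), bm))
  packed[bm == 0] <- 0
  class(packed) <- "i64"
  structure(list(allele = allele, values = packed, l_T = targets$l_T,
                 target_hash = target_hash(targets)),
            class = "annotation_vector")
}
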