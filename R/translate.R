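#' Server-side secure annotation: multiply loci by annotation vector
#'
#' The server holds the plaintext packed annotation vector for one allele and
#' multiplies it slot-wise into the client's encrypted loci vector. The
#' product decrypts to the packed impact value wherever the client had a
#' variant and to 0 elsewhere; the server learns nothing about which. The
#' ciphertext's metadata must carry the same allele and target-set hash as
#' the annotation vector, otherwise the call refuses to run.
#'
#' @param enc_loci a `cipher_vector` from [encrypt_loci()].
#' @param ann an `annotation_vector` for the same allele and target set.
#' @return a `cipher_vector` of packed impacts under the client's key.
#' @export
secure_annotate <- function(enc_loci, ann) {
  stopifnot(inherits(enc_loci, "cipher_vector"),
            inherits(ann, "annotation_vector"))
  if (!identical(enc_loci$meta$target_hash, ann$target_hash)) {
    stop("configuration error: ciphertext and annotation vector were built ",
         "against different target sets")
  }
  if (!identical(enc_loci$meta$allele, ann$allele)) {
    stop("configuration error: allele mismatch (", enc_loci$meta$allele,
         " vs ", ann$allele, ")")
  }
  he_mul_plain(enc_loci, ann$values)
}

# positional terms carried over from merged 1-bp bitmaps; frame-dependent and
# recomputed terms are stripped and re-derived by the merge logic
MERGE_DROP_TERMS <- c("frameshift_variant", "inframe_deletion",
                      "inframe_insertion", "start_lost", "stop_lost",
                      "stop_gained", "stop_retained_variant",
                      "coding_sequence_variant", "synonymous_variant",
                      "missense_variant")

union_bitmap_terms <- function(bitmaps) {
  bits <- sort(unique(unlist(lapply(bitmaps, bitmap_bits))))
  setdiff(.term_list[bits], MERGE_DROP_TERMS)
}

#' Translate a decrypted SNV annotation vector into records
#'
#' Client-side streaming step: every non-zero slot is a variant; its vector
#' coordinate is mapped back to (region, chromosome, position), the 58-bit
#' value is unpacked, and set bitmap bits become consequence terms.
#'
#' @param decrypted an `i64` vector of length `l_T` (the decrypted product).
#' @param targets the `target_set` the vector was built on.
#' @param allele the SNV alternate allele the vector belongs to.
#' @return an annotation-record tibble (see [annotate_variants_direct()]).
#' @export
translate_snv <- function(decrypted, targets, allele) {
  stopifnot(length(decrypted) == targets$l_T)
  nz <- i64_nonzero(decrypted)
  if (length(nz) == 0) return(empty_records())
  g <- vector_to_genomic(targets, nz)
  u <- unpack_impact(decrypted[nz])
  acc <- rec_acc()
  for (j in seq_along(nz)) {
    acc$add(g$chrom[j], g$pos[j], g$pos[j], "snv", allele,
            g$element_id[j], bitmap_to_terms(u$bitmap[j]))
  }
  acc$build() |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$type,
                    .data$allele, .data$element_id, .keep_all = TRUE)
}

# junction flanks in coding orientation from stored genomic neighborhoods:
# nb_first / nb_last are the 6-mers at the first/last affected base in
# *genomic* order; on the minus strand the roles swap and complement
junction_flanks <- function(nb_gmin, nb_gmax, minus) {
  if (minus) {
    list(left = reverse_complement(substr(nb_gmax, 4, 6)),
         right = reverse_complement(substr(nb_gmin, 1, 3)))
  } else {
    list(left = substr(nb_gmin, 1, 3), right = substr(nb_gmax, 4, 6))
  }
}

#' Translate a decrypted 1-bp-deletion annotation vector
#'
#' Deletions of arbitrary length are recovered by merging the 1-bp deletion
#' impacts along each deletion's span: the number of coding nucleotides
#' (frameshift vs in-frame by mod 3), start/stop/splice losses as unions,
#' and the junction codon rebuilt from the stored 6-bp neighborhoods and the
#' coding frame of the first deleted coding base, checked against the stop
#' codons for stop gain (or stop retention when the original stop was lost).
#' The client's own variant set delimits the spans — runs of non-zero slots
#' alone cannot separate adjacent deletions — and is also used as a
#' consistency check: a zero slot inside a span, or a non-zero slot outside
#' every span, is an error.
#'
#' @param decrypted `i64` vector of length `l_T` (product over allele `d`).
#' @param vs the client's `variant_set` (supplies deletion spans).
#' @param targets the `target_set`.
#' @return an annotation-record tibble; `engulfed` marks deletions fully
#'   contained in the element's regions.
#' @export
translate_deletion <- function(decrypted, vs, targets) {
  stopifnot(length(decrypted) == targets$l_T)
  acc <- rec_acc()
  if (nrow(vs$deletions) == 0) {
    check_unclaimed(decrypted, integer(0), "deletion")
    return(acc$build())
  }
  sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$deletions)),
                                         chrom = vs$deletions$chrom,
                                         s = vs$deletions$d1,
                                         e = vs$deletions$d2))
  if (is.null(sm)) {
    check_unclaimed(decrypted, integer(0), "deletion")
    return(acc$build())
  }
  u_all <- unpack_impact(decrypted[sm$nu])
  zero <- !i64_as_logical(decrypted[sm$nu])
  groups <- split(seq_len(nrow(sm)), paste(sm$id, sm$element_id))
  for (g in groups) {
    id <- sm$id[g[1]]
    d <- vs$deletions[id, ]
    el <- sm$element_id[g[1]]
    g1 <- g[!duplicated(sm$pos[g])]          # one slot per genomic position
    g1 <- g1[order(sm$pos[g1])]
    if (any(zero[g1])) {
      stop("inconsistency error: zero annotation slot inside deletion ",
           d$chrom, ":", d$d1, "-", d$d2, " (element ", el, ")")
    }
    minus <- sm$strand[g1[1]] == "-"
    bitmap <- u_all$bitmap[g1]
    coding <- bitmap_has_vec(bitmap, "frameshift_variant")
    n_coding <- sum(coding)
    jcodon <- NA_character_
    if (n_coding > 0) {
      f <- if (minus) u_all$frame[g1][max(which(coding))]
           else u_all$frame[g1][min(which(coding))]
      if (f > 0 || n_coding %% 3 != 0) {
        fl <- junction_flanks(u_all$neighborhood[g1][min(which(coding))],
                              u_all$neighborhood[g1][max(which(coding))],
                              minus)
        jcodon <- paste0(substr(fl$left, 4 - f, 3),
                         substr(fl$right, 1, 3 - f))
      }
    }
    terms <- deletion_terms(
      n_coding,
      any_start = any(bitmap_has_vec(bitmap, "start_lost")),
      any_stop = any(bitmap_has_vec(bitmap, "stop_lost")),
      junction_codon = jcodon,
      positional_terms = union_bitmap_terms(bitmap)
    )
    acc$add(d$chrom, d$d1, d$d2, "del", NA_character_, el, terms,
            engulfed = length(g1) == (d$d2 - d$d1 + 1))
  }
  check_unclaimed(decrypted, sm$nu, "deletion")
  acc$build()
}

bitmap_has_vec <- function(bitmap, term) {
  i <- term_index(term)
  floor(bitmap / 2^i) %% 2 == 1
}

i64_as_logical <- function(x) {
  out <- rep(FALSE, length(x))
  out[i64_nonzero(x)] <- TRUE
  out
}

check_unclaimed <- function(decrypted, claimed, what) {
  nz <- i64_nonzero(decrypted)
  stray <- setdiff(nz, claimed)
  if (length(stray) > 0) {
    stop("inconsistency error: non-zero ", what, " slot at nu = ", stray[1],
         " does not belong to any variant in the set")
  }
}

#' Translate a decrypted 1-bp-insertion annotation vector
#'
#' An insertion is annotated from the packed value at its single position:
#' the inserted length mod 3 decides frameshift vs in-frame, and the
#' inserted sequence is translated in frame at the junction — using the
#' stored neighborhood and coding frame — to detect created (or retained)
#' stop codons.
#'
#' @param decrypted `i64` vector of length `l_T` (product over allele `i`).
#' @param vs the client's `variant_set` (supplies inserted sequences).
#' @param targets the `target_set`.
#' @return an annotation-record tibble.
#' @export
translate_insertion <- function(decrypted, vs, targets) {
  stopifnot(length(decrypted) == targets$l_T)
  acc <- rec_acc()
  if (nrow(vs$insertions) == 0) {
    check_unclaimed(decrypted, integer(0), "insertion")
    return(acc$build())
  }
  sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$insertions)),
                                         chrom = vs$insertions$chrom,
                                         s = vs$insertions$pos,
                                         e = vs$insertions$pos))
  if (is.null(sm)) {
    check_unclaimed(decrypted, integer(0), "insertion")
    return(acc$build())
  }
  claimed <- sm$nu
  sm1 <- dplyr::distinct(sm, .data$id, .data$element_id, .keep_all = TRUE)
  u_all <- unpack_impact(decrypted[sm1$nu])
  nonzero <- i64_as_logical(decrypted[sm1$nu])
  for (j in seq_len(nrow(sm1))) {
    v <- vs$insertions[sm1$id[j], ]
    if (!nonzero[j]) {
      stop("inconsistency error: zero annotation slot at insertion ",
           v$chrom, ":", v$pos)
    }
    minus <- sm1$strand[j] == "-"
    bitmap <- u_all$bitmap[j]
    nb <- u_all$neighborhood[j]
    coding <- bitmap_has_vec(bitmap, "frameshift_variant")
    L <- nchar(v$seq)
    jcodons <- character(0)
    if (coding) {
      f <- u_all$frame[j]
      needed <- (3L - (f + L) %% 3L) %% 3L
      left_full <- if (minus) reverse_complement(substr(nb, 4, 6))
                   else substr(nb, 1, 3)
      right_full <- if (minus) reverse_complement(substr(nb, 1, 3))
                    else substr(nb, 4, 6)
      ins_cs <- if (minus) reverse_complement(v$seq) else v$seq
      jseq <- paste0(substr(left_full, 4 - f, 3), ins_cs,
                     substr(right_full, 1, needed))
      jcodons <- substring(jseq, seq(1, nchar(jseq), by = 3),
                           seq(3, nchar(jseq), by = 3))
    }
    terms <- insertion_terms(
      coding, L,
      interrupts_start = bitmap_has_vec(bitmap, "start_lost"),
      interrupts_stop = bitmap_has_vec(bitmap, "stop_lost"),
      junction_codons = jcodons,
      positional_terms = union_bitmap_terms(bitmap)
    )
    acc$add(v$chrom, v$pos, v$pos, "ins", v$seq, sm1$element_id[j], terms)
  }
  check_unclaimed(decrypted, claimed, "insertion")
  acc$build()
}

#' Run the whole secure annotation protocol on a variant set
#'
#' Convenience wrapper over the full client/server exchange for all six
#' alleles: vectorize loci, encrypt under a fresh client key, multiply with
#' the server's annotation vectors, decrypt, and translate. Equivalent to —
#' and tested against — [annotate_variants_direct()].
#'
#' @param vs a `variant_set`.
#' @param targets a `target_set`.
#' @param ann_vectors named list of `annotation_vector`s from
#'   [build_annotation_vectors()].
#' @param slot the ciphertext slot bound.
#' @return an annotation-record tibble, sorted like the direct path.
#' @export
secure_annotate_variants <- function(vs, targets, ann_vectors, slot = 32768) {
  kp <- keygen("client")
  res <- list()
  for (a in names(ann_vectors)) {
    loci <- vectorize_loci(vs, targets, a)
    if (sum(loci$bits) == 0) next
    ct <- secure_annotate(encrypt_loci(loci, kp$public, slot = slot),
                          ann_vectors[[a]])
    dec <- he_decrypt(ct, kp$secret)
    res[[a]] <- if (a == "d") translate_deletion(dec, vs, targets)
                else if (a == "i") translate_insertion(dec, vs, targets)
                else translate_snv(dec, targets, a)
  }
  if (length(res) == 0) return(empty_records())
  dplyr::bind_rows(res) |>
    dplyr::arrange(.data$chrom, .data$start, .data$type, .data$element_id)
}

#' Collapse per-element records to one record per variant
#'
#' Gene-level summarizing: unions the terms over all elements a variant
#' touches and keeps the worst severity. Both shapes are useful; neither is
#' canonical (per-element reporting is the default everywhere).
#'
#' @param records an annotation-record tibble.
#' @return one row per (chrom, start, end, type, allele).
#' @export
collapse_records <- function(records) {
  records |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$type,
                    .data$allele) |>
    dplyr::summarise(
      element_id = paste(sort(unique(.data$element_id)), collapse = ","),
      terms = list(.term_list[sort(unique(term_index(unlist(.data$terms)))) + 1L]),
      .groups = "drop"
    ) |>
    dplyr::mutate(severity = vapply(.data$terms, severity_of, character(1)))
}

#' Write annotation records as a tab-delimited report
#'
#' @param records an annotation-record tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(records, path) {
  flat <- records |>
    dplyr::mutate(terms = vapply(.data$terms, paste, character(1),
                                 collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
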