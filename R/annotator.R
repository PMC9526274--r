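#' @import tibble
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# per-transcript context used by the annotator and the full-variant oracle.
# cds_pos / cds_seq are in translation order (genomic for +, reversed and
# complemented for -). The last three coding bases are the stop codon.
transcript_context <- function(model, store, tx_id) {
  t <- model$transcripts[model$transcripts$transcript_id == tx_id, ]
  if (nrow(t) != 1) stop("unknown transcript: ", tx_id)
  exons <- model$exons[model$exons$transcript_id == tx_id, ]
  cds <- model$cds[model$cds$transcript_id == tx_id, ]
  minus <- t$strand == "-"
  chromseq <- store$seq[[t$chrom]]
  if (is.null(chromseq)) stop("chromosome not in genome: ", t$chrom)

  cds_pos <- integer(0)
  cds_seq <- ""
  if (nrow(cds) > 0) {
    ord_rows <- if (minus) order(-cds$start) else order(cds$start)
    pos_list <- lapply(ord_rows, function(i) {
      p <- seq.int(cds$start[i], cds$end[i])
      if (minus) rev(p) else p
    })
    cds_pos <- unlist(pos_list)
    seqs <- vapply(ord_rows, function(i) {
      substr(chromseq, cds$start[i], cds$end[i])
    }, character(1))
    if (minus) seqs <- reverse_complement(seqs)
    cds_seq <- paste(seqs, collapse = "")
  }
  n_cod <- nchar(cds_seq) %/% 3
  codons <- if (n_cod > 0) {
    substring(cds_seq, 3 * (seq_len(n_cod) - 1) + 1, 3 * seq_len(n_cod))
  } else character(0)

  # splice windows around each intron: donor = first 2 intronic bases (5' of
  # the intron in transcript orientation), acceptor = last 2 before the next
  # exon; splice_region = 1-3 exonic / 3-8 intronic bases from the boundary.
  donor <- acceptor <- sregion <- integer(0)
  if (nrow(exons) > 1) {
    for (j in seq_len(nrow(exons) - 1)) {
      istart <- exons$end[j] + 1L
      iend <- exons$start[j + 1] - 1L
      if (istart > iend) next
      left2 <- istart:min(iend, istart + 1L)    # intron bases next to exon j
      right2 <- max(istart, iend - 1L):iend     # intron bases next to exon j+1
      if (minus) {
        donor <- c(donor, right2); acceptor <- c(acceptor, left2)
      } else {
        donor <- c(donor, left2); acceptor <- c(acceptor, right2)
      }
      in_l <- istart + 2L; in_r <- iend - 2L
      sregion <- c(sregion,
                   seq_intersect(in_l, min(iend, istart + 7L), istart, iend),
                   seq_intersect(max(istart, iend - 7L), in_r, istart, iend),
                   (exons$end[j] - 2L):exons$end[j],
                   exons$start[j + 1]:(exons$start[j + 1] + 2L))
    }
  }

  list(
    tx_id = tx_id, chrom = t$chrom, strand = t$strand, minus = minus,
    chromseq = chromseq, exons = exons,
    span = c(min(exons$start), max(exons$end)),
    cds_pos = cds_pos, cds_seq = cds_seq, codons = codons, n_cod = n_cod,
    cds_gmin = if (length(cds_pos)) min(cds_pos) else NA_integer_,
    cds_gmax = if (length(cds_pos)) max(cds_pos) else NA_integer_,
    donor = unique(donor), acceptor = unique(acceptor),
    sregion = unique(sregion)
  )
}

seq_intersect <- function(a, b, lo, hi) {
  a <- max(a, lo); b <- min(b, hi)
  if (a > b) integer(0) else a:b
}

# vectorized positional classification against one transcript
classify_positions <- function(ctx, pos) {
  in_exon <- rep(FALSE, length(pos))
  for (j in seq_len(nrow(ctx$exons))) {
    in_exon <- in_exon | (pos >= ctx$exons$start[j] & pos <= ctx$exons$end[j])
  }
  ord <- match(pos, ctx$cds_pos)
  coding <- !is.na(ord)
  in_span <- pos >= ctx$span[1] & pos <= ctx$span[2]
  before <- pos < ctx$span[1]
  cls <- dplyr::case_when(
    coding ~ "cds",
    in_exon & !is.na(ctx$cds_gmin) &
      ((!ctx$minus & pos < ctx$cds_gmin) | (ctx$minus & pos > ctx$cds_gmax)) ~ "utr5",
    in_exon ~ "utr3",
    in_span ~ "intron",
    (before & !ctx$minus) | (!before & ctx$minus) ~ "upstream",
    TRUE ~ "downstream"
  )
  list(
    pos = pos, class = cls, ord = ord,
    pos_in_codon = ifelse(coding, (ord - 1L) %% 3L, 0L),
    codon_id = ifelse(coding, (ord - 1L) %/% 3L + 1L, NA_integer_),
    donor = pos %in% ctx$donor,
    acceptor = pos %in% ctx$acceptor,
    sregion = pos %in% ctx$sregion
  )
}

# bitmap contributions shared by every allele at a position
positional_bitmap <- function(cl) {
  bm <- numeric(length(cl$pos))
  add <- function(bm, flag, term) bm + ifelse(flag, 2^term_index(term), 0)
  bm <- add(bm, cl$class == "utr5", "5_prime_UTR_variant")
  bm <- add(bm, cl$class == "utr3", "3_prime_UTR_variant")
  bm <- add(bm, cl$class == "intron", "intron_variant")
  bm <- add(bm, cl$class == "upstream", "upstream_gene_variant")
  bm <- add(bm, cl$class == "downstream", "downstream_gene_variant")
  bm <- add(bm, cl$donor, "splice_donor_variant")
  bm <- add(bm, cl$acceptor, "splice_acceptor_variant")
  bm <- add(bm, cl$sregion, "splice_region_variant")
  bm
}

# SNV consequence bitmaps for one alt allele (plus-strand allele as in VCF)
snv_bitmaps <- function(ctx, cl, alt) {
  bm <- positional_bitmap(cl)
  coding <- cl$class == "cds"
  if (any(coding)) {
    f <- cl$pos_in_codon[coding]
    cid <- cl$codon_id[coding]
    refcod <- ctx$codons[cid]
    alt_cs <- if (ctx$minus) chartr("ACGT", "TGCA", alt) else alt
    newcod <- paste0(substr(refcod, 1, f), alt_cs,
                     substr(refcod, f + 2, 3))
    gc <- Biostrings::GENETIC_CODE
    is_start <- cid == 1L
    is_stop <- cid == ctx$n_cod
    new_stop <- newcod %in% STOP_CODONS
    term <- dplyr::case_when(
      is_start ~ "start_lost",
      is_stop & new_stop ~ "stop_retained_variant",
      is_stop ~ "stop_lost",
      new_stop ~ "stop_gained",
      unname(gc[refcod]) == unname(gc[newcod]) ~ "synonymous_variant",
      TRUE ~ "missense_variant"
    )
    bm[coding] <- bm[coding] + 2^term_index(term)
  }
  bm
}

# 1-bp deletion bitmaps: every coding base deleted is a frameshift signal,
# start/stop codon membership is carried as start_lost/stop_lost
del1_bitmaps <- function(ctx, cl) {
  bm <- positional_bitmap(cl)
  coding <- cl$class == "cds"
  bm <- bm + ifelse(coding, 2^term_index("frameshift_variant"), 0)
  bm <- bm + ifelse(coding & !is.na(cl$codon_id) & cl$codon_id == 1L,
                    2^term_index("start_lost"), 0)
  bm <- bm + ifelse(coding & !is.na(cl$codon_id) & cl$codon_id == ctx$n_cod,
                    2^term_index("stop_lost"), 0)
  bm
}

# insertion-point context: insertion after genomic position pos (between pos
# and pos + 1). The insertion lands in the coding sequence when the flank
# base on its 5' side (in translation order) is coding and is not the last
# coding base: inserted bases then become part of the mRNA, even at an
# exon-end junction (the splice motif itself is untouched). frame = number
# of bases of the interrupted codon 5' of the junction (0 = between codons).
insertion_context <- function(ctx, pos) {
  o_l <- if (ctx$minus) match(pos + 1L, ctx$cds_pos) else match(pos, ctx$cds_pos)
  n <- length(ctx$cds_pos)
  coding <- !is.na(o_l) & o_l < n
  f <- ifelse(coding, o_l %% 3L, 0L)
  cid <- ifelse(coding & f > 0L, (o_l - 1L) %/% 3L + 1L, NA_integer_)
  list(coding = coding, frame = as.integer(f), interrupted_codon = cid,
       ord_left = o_l)
}

ins1_bitmaps <- function(ctx, cl) {
  bm <- positional_bitmap(cl)
  ic <- insertion_context(ctx, cl$pos)
  bm <- bm + ifelse(ic$coding, 2^term_index("frameshift_variant"), 0)
  bm <- bm + ifelse(!is.na(ic$interrupted_codon) & ic$interrupted_codon == 1L,
                    2^term_index("start_lost"), 0)
  bm <- bm + ifelse(!is.na(ic$interrupted_codon) &
                      ic$interrupted_codon == ctx$n_cod,
                    2^term_index("stop_lost"), 0)
  # every target position must carry a non-zero insertion impact, or set loci
  # bits would vanish in the product; fall back to the generic coding term
  bm <- ifelse(bm == 0, 2^term_index("coding_sequence_variant"), bm)
  bm
}

# padded vectorized substring: N outside [1, nchar(s)]
sub_padded <- function(s, start, end) {
  n <- nchar(s)
  lo <- pmax(1L, start); hi <- pmin(n, end)
  core <- ifelse(lo <= hi, substring(s, lo, hi), "")
  paste0(strrep("N", pmax(0L, lo - start)), core,
         strrep("N", pmax(0L, end - hi)))
}

# 6-bp neighborhoods in plus-strand orientation. For SNVs/deletions the
# center base is excluded (left = pos-3..pos-1, right = pos+1..pos+3); for
# insertions the junction between pos and pos+1 is flanked (left includes
# pos itself).
neighborhood_of <- function(chromseq, pos, allele) {
  if (allele == "i") {
    paste0(sub_padded(chromseq, pos - 2L, pos),
           sub_padded(chromseq, pos + 1L, pos + 3L))
  } else {
    paste0(sub_padded(chromseq, pos - 3L, pos - 1L),
           sub_padded(chromseq, pos + 1L, pos + 3L))
  }
}

#' Alleles of the point-mutation alphabet
#'
#' The four SNV alternate alleles plus the 1-bp deletion (`"d"`) and 1-bp
#' insertion (`"i"`) states.
#' @return character vector `c("A","C","G","T","d","i")`.
#' @export
point_alleles <- function() c("A", "C", "G", "T", "d", "i")

#' Build packed annotation vectors for the target regions
#'
#' For every target position and every allele of the point-mutation alphabet
#' (four SNV alleles, 1-bp deletion `d`, 1-bp insertion `i`), the consequence
#' of that mutation on the region's element is computed and packed into a
#' 58-bit impact value (consequence bitmap, 6-bp neighborhood, coding frame).
#' Positions where the allele equals the reference base carry 0 (no variant
#' is possible), as do SNV alleles at no-consequence positions.
#'
#' @param model a `gene_model`.
#' @param store a `seq_store` from [load_genome()].
#' @param targets a `target_set` built from `model`.
#' @param alleles which alleles to build (default all six).
#' @return `build_annotation_vectors()` a named list of `annotation_vector`
#'   objects; `build_annotation_vector()` a single one.
#' @export
build_annotation_vectors <- function(model, store, targets,
                                     alleles = point_alleles()) {
  stopifnot(all(alleles %in% point_alleles()))
  r <- targets$regions
  vals <- lapply(alleles, function(a) numeric(targets$l_T))  # i64 bit patterns
  names(vals) <- alleles

  for (tx in unique(r$source_tx)) {
    ctx <- transcript_context(model, store, tx)
    idx <- which(r$source_tx == tx)
    pos <- unlist(lapply(idx, function(k) seq.int(r$start[k], r$end[k])))
    slot <- unlist(lapply(idx, function(k) {
      targets$cum[k] + seq_len(r$end[k] - r$start[k] + 1L)
    }))
    cl <- classify_positions(ctx, pos)
    refbase <- substring(ctx$chromseq, pos, pos)
    frames <- cl$pos_in_codon
    for (a in alleles) {
      if (a == "d") {
        bm <- del1_bitmaps(ctx, cl)
        nb <- neighborhood_of(ctx$chromseq, pos, "d")
        fr <- frames
      } else if (a == "i") {
        ic <- insertion_context(ctx, pos)
        bm <- ins1_bitmaps(ctx, cl)
        nb <- neighborhood_of(ctx$chromseq, pos, "i")
        fr <- ic$frame
      } else {
        bm <- snv_bitmaps(ctx, cl, a)
        bm[refbase == a] <- 0  # reference allele: no variant possible
        nb <- neighborhood_of(ctx$chromseq, pos, a)
        fr <- frames
      }
      packed <- unclass(pack_impact(fr, encode_neighborhood(nb), bm))
      packed[bm == 0] <- 0
      vals[[a]][slot] <- packed
    }
  }

  h <- target_hash(targets)
  lapply(stats::setNames(alleles, alleles), function(a) {
    v <- vals[[a]]
    class(v) <- "i64"
    structure(list(allele = a, values = v, l_T = targets$l_T,
                   target_hash = h),
              class = "annotation_vector")
  })
}

#' @rdname build_annotation_vectors
#' @param allele a single allele.
#' @export
build_annotation_vector <- function(model, store, targets, allele) {
  build_annotation_vectors(model, store, targets, alleles = allele)[[allele]]
}

#' @export
print.annotation_vector <- function(x, ...) {
  nz <- length(i64_nonzero(x$values))
  cat("<annotation_vector> allele ", x$allele, ", l_T = ", x$l_T,
      ", non-zero = ", nz, "\n", sep = "")
  invisible(x)
}

#' Annotate a single point mutation at a vector coordinate
#'
#' The per-position primitive behind [build_annotation_vectors()]: classify
#' the mutation of `allele` at vector position `nu` against the element of
#' its region.
#'
#' @inheritParams build_annotation_vectors
#' @param nu a vector coordinate in `1..l_T`.
#' @param allele one of [point_alleles()].
#' @return a list with `frame`, `neighborhood` (6-mer), `bitmap` and the
#'   decoded `terms`.
#' @export
annotate_point_mutation <- function(model, store, targets, nu, allele) {
  stopifnot(length(nu) == 1, allele %in% point_alleles())
  g <- vector_to_genomic(targets, nu)
  k <- g$region
  ctx <- transcript_context(model, store, targets$regions$source_tx[k])
  cl <- classify_positions(ctx, g$pos)
  if (allele == "d") {
    bm <- del1_bitmaps(ctx, cl); fr <- cl$pos_in_codon
  } else if (allele == "i") {
    bm <- ins1_bitmaps(ctx, cl); fr <- insertion_context(ctx, g$pos)$frame
  } else {
    bm <- snv_bitmaps(ctx, cl, allele)
    if (substring(ctx$chromseq, g$pos, g$pos) == allele) bm <- 0
    fr <- cl$pos_in_codon
  }
  list(frame = as.integer(fr),
       neighborhood = neighborhood_of(ctx$chromseq, g$pos, allele),
       bitmap = bm,
       terms = bitmap_to_terms(bm))
}
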