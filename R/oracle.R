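#' @importFrom rlang .data
NULL

SEVERITY_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

severity_of <- function(terms) {
  if (length(terms) == 0) return(NA_character_)
  sev <- .term_severity[terms]
  SEVERITY_LEVELS[max(match(sev, SEVERITY_LEVELS))]
}

canonical_terms <- function(terms) {
  .term_list[sort(term_index(unique(terms))) + 1L]
}

# record accumulator: thousands of records are collected as flat lists and
# materialized as one tibble at the end
rec_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$add <- function(chrom, start, end, type, allele, element_id, terms,
                    engulfed = NA) {
    e$rows[[length(e$rows) + 1L]] <- list(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      type = type, allele = allele, element_id = element_id,
      terms = canonical_terms(terms), engulfed = engulfed)
  }
  e$build <- function() {
    if (length(e$rows) == 0) return(empty_records())
    g <- function(f, mode) vapply(e$rows, function(r) r[[f]], mode)
    terms <- lapply(e$rows, `[[`, "terms")
    tibble::tibble(
      chrom = g("chrom", character(1)), start = g("start", integer(1)),
      end = g("end", integer(1)), type = g("type", character(1)),
      allele = g("allele", character(1)),
      element_id = g("element_id", character(1)), terms = terms,
      severity = vapply(terms, severity_of, character(1)),
      engulfed = g("engulfed", logical(1))
    ) |>
      dplyr::arrange(.data$chrom, .data$start, .data$type, .data$element_id)
  }
  e
}

# single-row record helper (unit-level paths)
ann_record <- function(chrom, start, end, type, allele, element_id, terms,
                       engulfed = NA) {
  acc <- rec_acc()
  acc$add(chrom, start, end, type, allele, element_id, terms, engulfed)
  acc$build()
}

empty_records <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 type = character(), allele = character(),
                 element_id = character(), terms = list(),
                 severity = character(), engulfed = logical())
}

# batched span-to-slot mapping: spans is a tibble (id, chrom, s, e); one
# genomic_to_vector call for all positions, joined back to the span ids and
# annotated with the containing region's element columns
span_map <- function(targets, spans) {
  if (nrow(spans) == 0) return(NULL)
  n <- spans$e - spans$s + 1L
  tab <- tibble::tibble(
    id = rep(spans$id, n),
    chrom = rep(spans$chrom, n),
    pos = unlist(mapply(seq.int, spans$s, spans$e, SIMPLIFY = FALSE))
  )
  m <- genomic_to_vector(targets, tab$chrom, tab$pos) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$region, .data$nu)
  if (nrow(m) == 0) return(NULL)
  r <- targets$regions
  joined <- dplyr::inner_join(tab, m, by = c("chrom", "pos"),
                              relationship = "many-to-many")
  joined$element_id <- r$element_id[joined$region]
  joined$source_tx <- r$source_tx[joined$region]
  joined$strand <- r$strand[joined$region]
  joined
}

ctx_cache_fn <- function(model, store) {
  cache <- new.env(parent = emptyenv())
  function(tx) {
    if (is.null(cache[[tx]])) {
      cache[[tx]] <- transcript_context(model, store, tx)
    }
    cache[[tx]]
  }
}

# cds_seq padded with 3 bases of genomic continuation on each side (in
# translation order), so junction codons at the CDS edges can be formed;
# coding index o maps to character o + 3
ext_cds_seq <- function(ctx) {
  if (length(ctx$cds_pos) == 0) return(strrep("N", 6))
  if (ctx$minus) {
    up <- reverse_complement(sub_padded(ctx$chromseq, ctx$cds_gmax + 1L,
                                        ctx$cds_gmax + 3L))
    down <- reverse_complement(sub_padded(ctx$chromseq, ctx$cds_gmin - 3L,
                                          ctx$cds_gmin - 1L))
  } else {
    up <- sub_padded(ctx$chromseq, ctx$cds_gmin - 3L, ctx$cds_gmin - 1L)
    down <- sub_padded(ctx$chromseq, ctx$cds_gmax + 1L, ctx$cds_gmax + 3L)
  }
  paste0(up, ctx$cds_seq, down)
}

ext_chars <- function(ext, idx) {
  # idx are coding-order indices (may run past either CDS edge by <= 3)
  substring(ext, idx + 3L, idx + 3L)
}

# union of positional consequence terms over a set of classified positions
union_positional_terms <- function(cl) {
  terms <- character(0)
  if (any(cl$class == "utr5")) terms <- c(terms, "5_prime_UTR_variant")
  if (any(cl$class == "utr3")) terms <- c(terms, "3_prime_UTR_variant")
  if (any(cl$class == "intron")) terms <- c(terms, "intron_variant")
  if (any(cl$class == "upstream")) terms <- c(terms, "upstream_gene_variant")
  if (any(cl$class == "downstream")) terms <- c(terms, "downstream_gene_variant")
  if (any(cl$donor)) terms <- c(terms, "splice_donor_variant")
  if (any(cl$acceptor)) terms <- c(terms, "splice_acceptor_variant")
  if (any(cl$sregion)) terms <- c(terms, "splice_region_variant")
  terms
}

# shared indel merge semantics; both the direct oracle and the secure-side
# translator reduce to these with differently sourced inputs
deletion_terms <- function(n_coding, any_start, any_stop, junction_codon,
                           positional_terms) {
  terms <- positional_terms
  if (n_coding > 0) {
    terms <- c(terms,
               if (n_coding %% 3 == 0) "inframe_deletion" else "frameshift_variant")
    if (any_start) terms <- c(terms, "start_lost")
    if (any_stop) terms <- c(terms, "stop_lost")
    if (!is.na(junction_codon) && junction_codon %in% STOP_CODONS) {
      terms <- c(terms, if (any_stop) "stop_retained_variant" else "stop_gained")
    }
  }
  unique(terms)
}

insertion_terms <- function(coding, ins_len, interrupts_start, interrupts_stop,
                            junction_codons, positional_terms) {
  terms <- positional_terms
  if (coding) {
    terms <- c(terms,
               if (ins_len %% 3 == 0) "inframe_insertion" else "frameshift_variant")
    if (interrupts_start) terms <- c(terms, "start_lost")
    if (interrupts_stop) terms <- c(terms, "stop_lost")
    if (any(junction_codons %in% STOP_CODONS)) {
      terms <- c(terms,
                 if (interrupts_stop) "stop_retained_variant" else "stop_gained")
    }
  }
  if (length(terms) == 0) terms <- "coding_sequence_variant"
  unique(terms)
}

#' Annotate full variants directly against the gene model
#'
#' The reference path: every variant of a set is evaluated directly on the
#' gene model and genome sequence, per overlapping element — SNVs by codon
#' substitution, deletions and insertions by counting affected coding bases
#' and rebuilding the junction codon on the true (spliced) coding sequence.
#' This is the ground truth that the secure pipeline's merge translation is
#' tested against. Variant visibility matches the pipeline's: only the part
#' of a variant overlapping the element's target regions is evaluated, and
#' the junction window is one codon.
#'
#' @param model a `gene_model`.
#' @param store a `seq_store`.
#' @param targets a `target_set` built from `model`.
#' @param vs a `variant_set`.
#' @return an annotation-record tibble: `chrom`, `start`, `end`, `type`
#'   (snv/del/ins), `allele` (alt base or inserted sequence), `element_id`,
#'   `terms` (list column, canonical order), `severity`, `engulfed` (for
#'   deletions: fully contained in the element's regions).
#' @export
annotate_variants_direct <- function(model, store, targets, vs) {
  get_ctx <- ctx_cache_fn(model, store)
  acc <- rec_acc()

  # --- SNVs: batched per (transcript, alt) ---
  if (nrow(vs$snvs) > 0) {
    sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$snvs)),
                                           chrom = vs$snvs$chrom,
                                           s = vs$snvs$pos, e = vs$snvs$pos))
    if (!is.null(sm)) {
      sm$alt <- vs$snvs$alt[sm$id]
      hits <- dplyr::distinct(sm, .data$chrom, .data$pos, .data$alt,
                              .data$element_id, .data$source_tx)
      for (tx in unique(hits$source_tx)) {
        ctx <- get_ctx(tx)
        h <- hits[hits$source_tx == tx, ]
        for (a in unique(h$alt)) {
          ha <- h[h$alt == a, ]
          cl <- classify_positions(ctx, ha$pos)
          bm <- snv_bitmaps(ctx, cl, a)
          ref <- substring(ctx$chromseq, ha$pos, ha$pos)
          for (j in seq_len(nrow(ha))) {
            if (ref[j] == a) next
            acc$add(ha$chrom[j], ha$pos[j], ha$pos[j], "snv", a,
                    ha$element_id[j], bitmap_to_terms(bm[j]))
          }
        }
      }
    }
  }

  # --- deletions: batched span mapping, merged per (deletion, element) ---
  if (nrow(vs$deletions) > 0) {
    sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$deletions)),
                                           chrom = vs$deletions$chrom,
                                           s = vs$deletions$d1,
                                           e = vs$deletions$d2))
    if (!is.null(sm)) {
      groups <- split(seq_len(nrow(sm)), paste(sm$id, sm$element_id))
      for (g in groups) {
        id <- sm$id[g[1]]
        d <- vs$deletions[id, ]
        ctx <- get_ctx(sm$source_tx[g[1]])
        vis <- sort(unique(sm$pos[g]))
        cl <- classify_positions(ctx, vis)
        coding <- cl$class == "cds"
        n_coding <- sum(coding)
        jcodon <- NA_character_
        if (n_coding > 0) {
          ords <- sort(cl$ord[coding])
          o1 <- ords[1]; oL <- ords[length(ords)]
          f <- (o1 - 1L) %% 3L
          if (f > 0 || n_coding %% 3 != 0) {
            ext <- ext_cds_seq(ctx)
            left <- if (f > 0) ext_chars(ext, (o1 - f):(o1 - 1L)) else character(0)
            right <- ext_chars(ext, (oL + 1L):(oL + 3L - f))
            jcodon <- paste(c(left, right), collapse = "")
          }
        }
        terms <- deletion_terms(
          n_coding,
          any_start = any(coding & !is.na(cl$codon_id) & cl$codon_id == 1L),
          any_stop = any(coding & !is.na(cl$codon_id) & cl$codon_id == ctx$n_cod),
          junction_codon = jcodon,
          positional_terms = union_positional_terms(cl)
        )
        acc$add(d$chrom, d$d1, d$d2, "del", NA_character_,
                sm$element_id[g[1]], terms,
                engulfed = length(vis) == (d$d2 - d$d1 + 1))
      }
    }
  }

  # --- insertions: single-position mapping per (insertion, element) ---
  if (nrow(vs$insertions) > 0) {
    sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$insertions)),
                                           chrom = vs$insertions$chrom,
                                           s = vs$insertions$pos,
                                           e = vs$insertions$pos))
    if (!is.null(sm)) {
      sm <- dplyr::distinct(sm, .data$id, .data$element_id, .keep_all = TRUE)
      for (j in seq_len(nrow(sm))) {
        v <- vs$insertions[sm$id[j], ]
        ctx <- get_ctx(sm$source_tx[j])
        cl <- classify_positions(ctx, v$pos)
        ic <- insertion_context(ctx, v$pos)
        jcodons <- character(0)
        L <- nchar(v$seq)
        if (ic$coding) {
          f <- ic$frame
          ins_cs <- if (ctx$minus) reverse_complement(v$seq) else v$seq
          needed <- (3L - (f + L) %% 3L) %% 3L
          ext <- ext_cds_seq(ctx)
          left <- if (f > 0) {
            paste(ext_chars(ext, (ic$ord_left - f + 1L):ic$ord_left),
                  collapse = "")
          } else ""
          right <- if (needed > 0) {
            paste(ext_chars(ext, (ic$ord_left + 1L):(ic$ord_left + needed)),
                  collapse = "")
          } else ""
          jseq <- paste0(left, ins_cs, right)
          jcodons <- substring(jseq, seq(1, nchar(jseq), by = 3),
                               seq(3, nchar(jseq), by = 3))
        }
        terms <- insertion_terms(
          ic$coding, L,
          interrupts_start = !is.na(ic$interrupted_codon) && ic$interrupted_codon == 1L,
          interrupts_stop = !is.na(ic$interrupted_codon) && ic$interrupted_codon == ctx$n_cod,
          junction_codons = jcodons,
          positional_terms = union_positional_terms(cl)
        )
        acc$add(v$chrom, v$pos, v$pos, "ins", v$seq, sm$element_id[j], terms)
      }
    }
  }

  acc$build()
}

#' Identify indel junctions whose genomic and spliced contexts diverge
#'
#' The secure-side translation rebuilds junction codons from the stored
#' *genomic* 6-bp neighborhoods, while the true post-variant codon lives on
#' the *spliced* coding sequence. The two can differ exactly when the
#' one-codon junction window crosses an exon boundary (or runs past the CDS
#' edge into sequence that splicing would not keep adjacent) — the documented
#' limitation classes of the merge translation (junction-spanning stop
#' gains, and downstream stop codons beyond the window). This predicate
#' flags, per (variant, element), whether the junction window leaves the
#' splice-safe zone, from variant geometry alone; it is deliberately a
#' superset of the cases that actually disagree.
#'
#' @inheritParams annotate_variants_direct
#' @return a tibble (`chrom`, `start`, `end`, `type`, `element_id`,
#'   `divergent`).
#' @export
junction_divergent <- function(model, store, targets, vs) {
  get_ctx <- ctx_cache_fn(model, store)
  seq2 <- function(a, b) if (a > b) integer(0) else a:b
  # coding-order indices idx must sit on genomically contiguous positions,
  # anchored at coding-order index o0 (idx ordered moving away by `dir`)
  contiguous <- function(ctx, o0, idx, dir) {
    if (length(idx) == 0) return(TRUE)
    n <- length(ctx$cds_pos)
    step <- if (ctx$minus) -1L else 1L
    inside <- idx >= 1 & idx <= n
    expect <- ctx$cds_pos[o0] + dir * step * seq_along(idx)
    got <- ifelse(inside, ctx$cds_pos[idx], expect)  # beyond-CDS: genomic by construction
    all(got == expect)
  }
  rows <- list()
  if (nrow(vs$deletions) > 0) {
    sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$deletions)),
                                           chrom = vs$deletions$chrom,
                                           s = vs$deletions$d1,
                                           e = vs$deletions$d2))
    if (!is.null(sm)) {
      groups <- split(seq_len(nrow(sm)), paste(sm$id, sm$element_id))
      for (g in groups) {
        id <- sm$id[g[1]]
        d <- vs$deletions[id, ]
        ctx <- get_ctx(sm$source_tx[g[1]])
        cl <- classify_positions(ctx, sort(unique(sm$pos[g])))
        div <- FALSE
        if (any(cl$class == "cds")) {
          ords <- sort(cl$ord[cl$class == "cds"])
          o1 <- ords[1]; oL <- ords[length(ords)]
          f <- (o1 - 1L) %% 3L
          if (f > 0 || length(ords) %% 3 != 0) {  # a junction codon is formed
            div <- (oL - o1 + 1L) != length(ords) ||
              !contiguous(ctx, o1, rev(seq2(o1 - f, o1 - 1L)), -1L) ||
              !contiguous(ctx, oL, seq2(oL + 1L, oL + 3L - f), 1L)
          }
        }
        rows[[length(rows) + 1]] <- list(
          chrom = d$chrom, start = d$d1, end = d$d2, type = "del",
          element_id = sm$element_id[g[1]], divergent = div)
      }
    }
  }
  if (nrow(vs$insertions) > 0) {
    sm <- span_map(targets, tibble::tibble(id = seq_len(nrow(vs$insertions)),
                                           chrom = vs$insertions$chrom,
                                           s = vs$insertions$pos,
                                           e = vs$insertions$pos))
    if (!is.null(sm)) {
      sm <- dplyr::distinct(sm, .data$id, .data$element_id, .keep_all = TRUE)
      for (j in seq_len(nrow(sm))) {
        v <- vs$insertions[sm$id[j], ]
        ctx <- get_ctx(sm$source_tx[j])
        ic <- insertion_context(ctx, v$pos)
        div <- FALSE
        if (ic$coding) {
          f <- ic$frame
          needed <- (3L - (f + nchar(v$seq)) %% 3L) %% 3L
          div <-
            !contiguous(ctx, ic$ord_left,
                        rev(seq2(ic$ord_left - f + 1L, ic$ord_left - 1L)), -1L) ||
            !contiguous(ctx, ic$ord_left,
                        seq2(ic$ord_left + 1L, ic$ord_left + needed), 1L)
        }
        rows[[length(rows) + 1]] <- list(
          chrom = v$chrom, start = v$pos, end = v$pos, type = "ins",
          element_id = sm$element_id[j], divergent = div)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), type = character(),
                          element_id = character(), divergent = logical()))
  }
  tibble::tibble(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    type = vapply(rows, `[[`, "", "type"),
    element_id = vapply(rows, `[[`, "", "element_id"),
    divergent = vapply(rows, `[[`, TRUE, "divergent")
  )
}
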