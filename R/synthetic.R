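#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: a 1 Mb chromosome carrying 50 multi-transcript protein-coding
#' genes on both strands (some nested inside another gene's intron, some
#' tagged as nonsense-mediated decay to exercise the transcript filters), a
#' 25% per-position mutation probability with the alternate allele uniform
#' over the three non-reference bases, indel lengths uniform on [1, 10] with
#' random inserted sequence, and at most a few hundred diploid samples with
#' a Beta allele-frequency spectrum under Hardy-Weinberg genotypes.
#'
#' @param seed integer seed; every simulation op is deterministic given it.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length (bp).
#' @param n_genes gene count.
#' @param p_minus probability a gene is on the minus strand.
#' @param exons_per_tx range of CDS-exon counts per transcript.
#' @param cds_exon_len range of CDS-exon lengths (bp).
#' @param intron_len,utr_len ranges (bp).
#' @param p_aligned probability a gene's CDS exons are codon-aligned
#'   (multiples of 3; such genes can host exon-skipping transcripts).
#' @param p_second_tx probability of a second coding transcript.
#' @param p_nmd probability of an additional NMD-tagged transcript.
#' @param p_nested probability the next gene nests into the previous gene's
#'   largest intron (creates overlapping genes).
#' @param p_mut per-position mutation probability (default 0.25).
#' @param del_len,ins_len deletion/insertion length ranges (default [1, 10]).
#' @param n_samples diploid sample count for genotype simulation.
#' @param af_beta shape parameters of the Beta allele-frequency spectrum.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom = "chrS", chrom_len = 1e6, n_genes = 50,
                       p_minus = 0.5,
                       exons_per_tx = c(2, 5), cds_exon_len = c(30, 150),
                       intron_len = c(60, 400), utr_len = c(10, 60),
                       p_aligned = 0.5, p_second_tx = 0.6, p_nmd = 0.15,
                       p_nested = 0.15,
                       p_mut = 0.25, del_len = c(1, 10), ins_len = c(1, 10),
                       n_samples = 100, af_beta = c(0.5, 5)) {
  stopifnot(p_mut >= 0, p_mut <= 1, del_len[1] >= 1, ins_len[1] >= 1,
            n_samples >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rint <- function(range) if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
        1, paste, collapse = ""),
  STOP_CODONS
)

#' Simulate a reference genome and gene annotation
#'
#' Generates the synthetic chromosome and gene model described in
#' [sim_config()] and writes them as FASTA and GTF. Every coding transcript
#' has a valid ORF: the CDS starts with ATG, ends with a stop codon on its
#' strand, contains no in-frame internal stop, and its length is a multiple
#' of 3 (the stop codon is part of the CDS). Second transcripts either share
#' the CDS exactly (differing UTR extents) or skip a codon-aligned internal
#' exon; NMD-tagged transcripts are emitted for filter tests.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created).
#' @return a list: `fasta`, `gtf` (paths) and `genes` (a tibble of gene
#'   metadata).
#' @export
simulate_reference <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    genome <- sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE)

    tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
    gene_meta <- list()
    cursor <- 2000L
    host <- NULL  # an enlarged intron of a previous gene, open for nesting

    add_tx <- function(gid, tid, strand, exons, cds, tags = character(0)) {
      tx_rows[[length(tx_rows) + 1]] <<- tibble::tibble(
        gene_id = gid, transcript_id = tid, chrom = config$chrom,
        strand = strand, tags = list(tags))
      exon_rows[[length(exon_rows) + 1]] <<- tibble::tibble(
        transcript_id = tid, chrom = config$chrom,
        start = exons$start, end = exons$end)
      if (!is.null(cds)) {
        cds_rows[[length(cds_rows) + 1]] <<- tibble::tibble(
          transcript_id = tid, chrom = config$chrom,
          start = cds$start, end = cds$end, frame = cds$frame)
      }
    }

    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("GENE%03d", g)
      strand <- if (stats::runif(1) < config$p_minus) "-" else "+"
      aligned <- stats::runif(1) < config$p_aligned
      # a gene nests (compact, single exon) into a previously opened host
      # intron, giving overlapping gene pairs with disjoint exon sequence
      nested <- !is.null(host)
      n_ex <- if (nested) 1L else rint(config$exons_per_tx)

      lens <- vapply(seq_len(n_ex), function(i) rint(config$cds_exon_len),
                     integer(1))
      if (aligned) {
        lens <- pmax(30L, (lens %/% 3L) * 3L)
      } else if (sum(lens) %% 3L != 0L) {
        lens[n_ex] <- lens[n_ex] + (3L - sum(lens) %% 3L)
      }
      introns <- if (n_ex > 1) {
        vapply(seq_len(n_ex - 1), function(i) rint(config$intron_len),
               integer(1))
      } else integer(0)
      make_host <- !nested && n_ex > 1 &&
        stats::runif(1) < config$p_nested
      if (make_host) introns[1] <- introns[1] + 2200L
      utrA <- rint(config$utr_len); utrB <- rint(config$utr_len)
      span_len <- utrA + sum(lens) + sum(introns) + utrB

      if (nested && (host$start + 20L + span_len + 20L <= host$end)) {
        gstart <- host$start + 20L
      } else {
        nested <- FALSE
        gstart <- cursor
      }
      host <- NULL
      if (gstart + span_len + 2000L > config$chrom_len) {
        if (length(gene_meta) == 0) {
          stop("config error: genes do not fit the chromosome")
        }
        break
      }

      # genomic CDS intervals, left to right
      cds_start <- gstart + utrA
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- cds_start
      for (i in seq_len(n_ex)) {
        starts[i] <- p; ends[i] <- p + lens[i] - 1L
        p <- ends[i] + 1L + (if (i < n_ex) introns[i] else 0L)
      }

      # coding sequence in translation order; write its plus-strand image
      n_cod <- sum(lens) %/% 3L
      codons <- c("ATG",
                  sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                  sample(STOP_CODONS, 1))
      coding <- paste(codons, collapse = "")
      plus_image <- if (strand == "-") reverse_complement(coding) else coding
      off <- 0L
      for (i in seq_len(n_ex)) {
        genome[starts[i]:ends[i]] <-
          strsplit(substr(plus_image, off + 1L, off + lens[i]), "")[[1]]
        off <- off + lens[i]
      }

      exons1 <- tibble::tibble(
        start = c(gstart, starts[-1]),
        end = c(ends[-n_ex], ends[n_ex] + utrB)
      )
      if (n_ex == 1) exons1 <- tibble::tibble(start = gstart,
                                              end = ends[1] + utrB)
      cds1 <- tibble::tibble(start = starts, end = ends, frame = 0L)

      add_tx(gid, paste0(gid, ".t1"), strand, exons1, cds1)

      if (stats::runif(1) < config$p_second_tx) {
        if (aligned && n_ex >= 3) {
          drop <- 1L + rint(c(1L, n_ex - 2L))  # internal exon
          keep <- setdiff(seq_len(n_ex), drop)
          exons2 <- exons1[keep, ]
          cds2 <- cds1[keep, ]
          add_tx(gid, paste0(gid, ".t2"), strand, exons2, cds2)
        } else {
          shift <- rint(c(3L, 9L))
          exons2 <- exons1
          exons2$start[1] <- max(1L, exons2$start[1] - shift)
          exons2$end[nrow(exons2)] <- exons2$end[nrow(exons2)] + shift
          add_tx(gid, paste0(gid, ".t2"), strand, exons2, cds1)
        }
      }
      if (stats::runif(1) < config$p_nmd) {
        add_tx(gid, paste0(gid, ".nmd"), strand, exons1, cds1,
               tags = "nonsense_mediated_decay")
      }

      gene_meta[[length(gene_meta) + 1]] <- tibble::tibble(
        gene_id = gid, strand = strand, start = gstart,
        end = gstart + span_len - 1L, nested = nested, aligned = aligned)
      if (!nested) {
        cursor <- gstart + span_len + rint(c(200L, 1500L))
        if (make_host) host <- list(start = ends[1] + 1L, end = starts[2] - 1L)
      }
    }

    fasta <- file.path(dir, "reference.fa")
    gtf <- file.path(dir, "annotation.gtf")
    write_fasta_string(paste(genome, collapse = ""), config$chrom, fasta)

    model <- structure(
      list(transcripts = dplyr::bind_rows(tx_rows),
           exons = dplyr::bind_rows(exon_rows) |>
             dplyr::arrange(.data$transcript_id, .data$start),
           cds = dplyr::bind_rows(cds_rows) |>
             dplyr::arrange(.data$transcript_id, .data$start)),
      class = "gene_model"
    )
    write_gene_model(model, gtf)
    list(fasta = fasta, gtf = gtf, genes = dplyr::bind_rows(gene_meta))
  })
}

write_fasta_string <- function(seq, name, path) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 60L)
  writeLines(c(paste0(">", name),
               substring(seq, starts, pmin(starts + 59L, n))), path)
  invisible(path)
}

#' Simulate variants on the target regions
#'
#' Each unique genomic position covered by the targets mutates independently
#' with probability `p` (per variant type): SNVs replace the reference base
#' with one of the three alternatives uniformly; deletion lengths are uniform
#' on the configured range; insertions add a random sequence after the
#' position. Known-answer variants can be injected alongside the random ones
#' via `inject`.
#'
#' @param targets a `target_set`.
#' @param store a `seq_store`.
#' @param config a `sim_config` (supplies `p_mut`, length ranges).
#' @param types subset of `c("snv", "del", "ins")`.
#' @param p per-position mutation probability (defaults to `config$p_mut`).
#' @param seed seed (defaults to `config$seed + 1`).
#' @param inject optional tibble (chrom, pos, ref, alt) of scripted VCF rows.
#' @return a tibble of VCF-convention rows (`chrom`, `pos`, `ref`, `alt`,
#'   `type`), coordinate-sorted.
#' @export
simulate_variants <- function(targets, store, config,
                              types = c("snv", "del", "ins"),
                              p = config$p_mut, seed = config$seed + 1,
                              inject = NULL) {
  r <- targets$regions
  cover <- dplyr::bind_rows(lapply(unique(r$chrom), function(ch) {
    ir <- IRanges::reduce(IRanges::IRanges(r$start[r$chrom == ch],
                                           r$end[r$chrom == ch]))
    tibble::tibble(chrom = ch,
                   pos = unlist(mapply(seq.int, IRanges::start(ir),
                                       IRanges::end(ir), SIMPLIFY = FALSE)))
  }))
  with_seed(seed, {
    out <- list()
    for (type in types) {
      hit <- cover[stats::runif(nrow(cover)) < p, ]
      if (nrow(hit) == 0) next
      # store$seq[hit$chrom] is a list of references, not copies
      ref1 <- substring(unlist(store$seq[hit$chrom]), hit$pos, hit$pos)
      if (type == "snv") {
        ok <- ref1 %in% c("A", "C", "G", "T")
        hit <- hit[ok, ]; ref1 <- ref1[ok]
        alt <- vapply(ref1, function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        out[[type]] <- tibble::tibble(chrom = hit$chrom, pos = hit$pos,
                                      ref = ref1, alt = unname(alt),
                                      type = "snv")
      } else if (type == "del") {
        len <- sample(config$del_len[1]:config$del_len[2], nrow(hit),
                      replace = TRUE)
        chrlen <- nchar(unlist(store$seq[hit$chrom]))
        ok <- hit$pos > 1 & (hit$pos + len - 1) <= chrlen
        hit <- hit[ok, ]; len <- len[ok]
        ref <- vapply(seq_len(nrow(hit)), function(i) {
          seq_sub(store, hit$chrom[i], hit$pos[i] - 1L, hit$pos[i] + len[i] - 1L)
        }, character(1))
        out[[type]] <- tibble::tibble(chrom = hit$chrom, pos = hit$pos - 1L,
                                      ref = ref, alt = substr(ref, 1, 1),
                                      type = "del")
      } else {
        len <- sample(config$ins_len[1]:config$ins_len[2], nrow(hit),
                      replace = TRUE)
        ins <- vapply(len, function(l) {
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                collapse = "")
        }, character(1))
        out[[type]] <- tibble::tibble(chrom = hit$chrom, pos = hit$pos,
                                      ref = ref1, alt = paste0(ref1, ins),
                                      type = "ins")
      }
    }
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            type = character())
    res <- dplyr::bind_rows(c(list(empty), out))
    if (!is.null(inject)) {
      res <- dplyr::bind_rows(res, dplyr::mutate(inject, type = "injected"))
    }
    dplyr::arrange(res, .data$chrom, .data$pos)
  })
}

#' Simulate multi-sample genotypes for a site list
#'
#' Per-site allele frequencies are drawn from the configured Beta spectrum
#' and diploid genotypes from Hardy-Weinberg proportions at that frequency.
#'
#' @param sites tibble (`chrom`, `pos`, `ref`, `alt`) of biallelic sites.
#' @param n_samples number of diploid samples.
#' @param af_beta Beta shape parameters (set `c(0, 0)` for all-reference).
#' @param seed RNG seed.
#' @param sample_prefix sample-name prefix.
#' @return a list: `gt` (character matrix of GT strings, sites x samples)
#'   and `af` (the drawn frequencies).
#' @export
simulate_genotypes <- function(sites, n_samples, af_beta = c(0.5, 5),
                               seed = 1, sample_prefix = "S") {
  stopifnot(nrow(sites) > 0, n_samples >= 1)
  with_seed(seed, {
    af <- if (all(af_beta == 0)) rep(0, nrow(sites))
          else stats::rbeta(nrow(sites), af_beta[1], af_beta[2])
    dos <- matrix(stats::rbinom(nrow(sites) * n_samples, 2,
                                rep(af, n_samples)),
                  nrow = nrow(sites))
    gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(sites))
    colnames(gt) <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
    list(gt = gt, af = af)
  })
}
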