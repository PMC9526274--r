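#' Load a gene annotation (GTF or GFF3) into a gene model
#'
#' Parses exon and CDS features into an in-memory gene model and applies the
#' transcript filters used throughout the package: transcripts tagged as
#' nonsense-mediated decay or as having an incomplete coding sequence are
#' removed, because their annotations are unreliable for consequence calling.
#' "Incomplete coding sequence" is operationalized as carrying any
#' start/stop-not-found tag, or having a CDS whose length (after adjusting
#' for the first segment's frame) is not a multiple of 3.
#'
#' GTF (`key "value";`) and GFF3 (`key=value`) attribute dialects are
#' auto-detected per file. Stop-codon features, when present as separate
#' rows (GENCODE style), are merged into the CDS, so the last three coding
#' bases of every retained transcript are its stop codon. All coordinates
#' are 1-based inclusive; minus-strand transcripts are stored in genomic
#' orientation.
#'
#' @param path a GTF/GFF3 file.
#' @param exclude_tags tags whose presence removes a transcript. Matching is
#'   against both explicit `tag` attributes and the transcript biotype.
#' @return a `gene_model`: a list of tibbles `transcripts` (gene_id,
#'   transcript_id, chrom, strand, tags), `exons` and `cds` (with `frame`).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 3)
#' paths <- simulate_reference(cfg, dir = tempfile())
#' model <- load_gene_annotation(paths$gtf)
#' model$transcripts
#' @export
load_gene_annotation <- function(path,
                                 exclude_tags = default_exclude_tags()) {
  raw <- parse_annotation_rows(path)

  tx_rows <- raw[raw$type %in% c("transcript", "mRNA"), , drop = FALSE]
  feat <- raw[raw$type %in% c("exon", "CDS", "stop_codon"), , drop = FALSE]
  if (nrow(feat) == 0) stop("annotation has no exon/CDS rows: ", path)

  # tags: explicit tag attributes plus transcript biotype strings
  tag_tbl <- dplyr::bind_rows(
    tibble::tibble(transcript_id = tx_rows$transcript_id, tag = tx_rows$tags),
    tibble::tibble(transcript_id = feat$transcript_id, tag = feat$tags)
  ) |>
    tidyr::unnest(tag) |>
    dplyr::filter(!is.na(.data$tag), .data$tag != "") |>
    dplyr::distinct()

  tx <- feat |>
    dplyr::distinct(.data$transcript_id, .data$gene_id, .data$chrom,
                    .data$strand) |>
    dplyr::arrange(.data$transcript_id)
  if (anyDuplicated(tx$transcript_id)) {
    stop("model-consistency error: transcript spans multiple chromosomes/strands/genes")
  }
  tx$tags <- lapply(tx$transcript_id, function(id) {
    sort(unique(tag_tbl$tag[tag_tbl$transcript_id == id]))
  })

  exons <- feat |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::select("transcript_id", "chrom", "start", "end") |>
    dplyr::arrange(.data$transcript_id, .data$start)

  cds <- feat |>
    dplyr::filter(.data$type %in% c("CDS", "stop_codon")) |>
    dplyr::select("transcript_id", "chrom", "start", "end", "frame") |>
    dplyr::arrange(.data$transcript_id, .data$start)
  cds <- merge_cds_segments(cds, tx)

  model <- structure(
    list(transcripts = tx, exons = exons, cds = cds),
    class = "gene_model"
  )
  validate_gene_model(model)
  filter_transcripts(model, exclude_tags)
}

#' @rdname load_gene_annotation
#' @export
default_exclude_tags <- function() {
  c("nonsense_mediated_decay", "NMD", "NMD_transcript",
    "cds_start_NF", "cds_end_NF", "mRNA_start_NF", "mRNA_end_NF",
    "incomplete_terminal_codon", "incomplete_cds")
}

# read the 9-column table with line-numbered validation, then parse attributes
parse_annotation_rows <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty annotation file: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- lineno[which(nf != 9)[1]]
    stop("parse error at line ", bad, ": expected 9 tab-separated fields")
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end) || any(start > end)) {
    bad <- lineno[which(is.na(start) | is.na(end) | start > end)[1]]
    stop("parse error at line ", bad, ": invalid start/end coordinates")
  }

  attrs <- m[, 9]
  gff3 <- !any(grepl("\"", attrs, fixed = TRUE)) && any(grepl("=", attrs, fixed = TRUE))
  get_attr <- function(a, key) {
    pat <- if (gff3) paste0("(?:^|;)\\s*", key, "=([^;]*)")
           else paste0("(?:^|;)\\s*", key, "\\s+\"([^\"]*)\"")
    mm <- regmatches(a, regexec(pat, a))
    vapply(mm, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  get_tags <- function(a) {
    pat <- if (gff3) "(?:^|;)\\s*tag=([^;]*)" else "tag\\s+\"([^\"]*)\""
    mm <- regmatches(a, gregexpr(pat, a))
    lapply(seq_along(mm), function(i) {
      tags <- sub(pat, "\\1", mm[[i]])
      if (gff3) tags <- unlist(strsplit(tags, ","))
      tags[nzchar(tags)]
    })
  }

  biotype <- get_attr(attrs, "transcript_biotype")
  biotype2 <- get_attr(attrs, "transcript_type")
  biotype[is.na(biotype)] <- biotype2[is.na(biotype)]
  tags <- get_tags(attrs)
  tags <- lapply(seq_along(tags), function(i) {
    unique(c(tags[[i]], biotype[i][!is.na(biotype[i]) &
                                     biotype[i] != "protein_coding"]))
  })

  tibble::tibble(
    chrom = m[, 1], type = m[, 3], start = start, end = end,
    strand = m[, 7],
    frame = suppressWarnings(as.integer(m[, 8])),
    gene_id = get_attr(attrs, "gene_id"),
    transcript_id = get_attr(attrs, "transcript_id"),
    tags = tags
  )
}

# merge CDS + stop_codon rows per transcript and recompute frames in
# translation order (first retained segment has frame 0)
merge_cds_segments <- function(cds, tx) {
  if (nrow(cds) == 0) return(cds)
  strand_of <- stats::setNames(tx$strand, tx$transcript_id)
  cds |>
    dplyr::group_by(.data$transcript_id, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      r <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
      out <- tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
      minus <- strand_of[[key$transcript_id]] == "-"
      ord <- if (minus) order(-out$start) else order(out$start)
      lens <- (out$end - out$start + 1)[ord]
      before <- cumsum(c(0, utils::head(lens, -1)))
      out$frame <- NA_integer_
      out$frame[ord] <- as.integer((3 - before %% 3) %% 3)
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", "chrom", "start", "end", "frame") |>
    dplyr::arrange(.data$transcript_id, .data$start)
}

validate_gene_model <- function(model) {
  # every CDS contained in an exon of its transcript
  if (nrow(model$cds) > 0) {
    ok <- vapply(seq_len(nrow(model$cds)), function(i) {
      cd <- model$cds[i, ]
      ex <- model$exons[model$exons$transcript_id == cd$transcript_id, ]
      any(ex$start <= cd$start & ex$end >= cd$end)
    }, logical(1))
    if (!all(ok)) {
      bad <- model$cds[which(!ok)[1], ]
      stop("model-consistency error: CDS ", bad$start, "-", bad$end,
           " of ", bad$transcript_id, " is not contained in any exon")
    }
  }
  # exons non-overlapping within transcript
  overl <- model$exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(bad = any(.data$start[-1] <= utils::head(.data$end, -1)),
                     .groups = "drop")
  if (any(overl$bad)) {
    stop("model-consistency error: overlapping exons in transcript ",
         overl$transcript_id[which(overl$bad)[1]])
  }
  invisible(model)
}

#' Filter transcripts of a gene model by tag
#'
#' @param model a `gene_model`.
#' @param exclude_tags tags removing a transcript (see
#'   [load_gene_annotation()]).
#' @return the filtered `gene_model`.
#' @export
filter_transcripts <- function(model, exclude_tags = default_exclude_tags()) {
  tagged <- vapply(model$transcripts$tags,
                   function(t) any(t %in% exclude_tags), logical(1))
  # incomplete coding sequence: CDS length after frame adjustment not 0 mod 3
  cds_len <- model$cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start + 1), .groups = "drop")
  incomplete <- cds_len$transcript_id[cds_len$len %% 3 != 0]
  drop <- model$transcripts$transcript_id[tagged] |>
    union(incomplete)

  keep <- !(model$transcripts$transcript_id %in% drop)
  model$transcripts <- model$transcripts[keep, ]
  model$exons <- model$exons[model$exons$transcript_id %in%
                               model$transcripts$transcript_id, ]
  model$cds <- model$cds[model$cds$transcript_id %in%
                           model$transcripts$transcript_id, ]
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", length(unique(x$transcripts$gene_id)), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons, ",
      nrow(x$cds), " CDS segments\n", sep = "")
  invisible(x)
}

#' Write a gene model back to GTF
#'
#' Attributes are emitted in canonical order (`gene_id`, `transcript_id`,
#' then sorted `tag` attributes) so that writing and re-parsing a model is
#' an identity.
#'
#' @param model a `gene_model`.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  tx <- model$transcripts
  rows <- character(0)
  attr_str <- function(gid, tid, tags = character(0)) {
    s <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    if (length(tags)) {
      s <- paste(s, paste(sprintf('tag "%s";', sort(tags)), collapse = " "))
    }
    s
  }
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- model$exons[model$exons$transcript_id == t$transcript_id, ]
    cd <- model$cds[model$cds$transcript_id == t$transcript_id, ]
    a <- attr_str(t$gene_id, t$transcript_id, t$tags[[1]])
    span <- range(c(ex$start, ex$end))
    rows <- c(rows,
      sprintf("%s\tvectann\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, span[1], span[2], t$strand, a),
      sprintf("%s\tvectann\texon\t%d\t%d\t.\t%s\t.\t%s",
              ex$chrom, ex$start, ex$end, t$strand, a),
      if (nrow(cd)) sprintf("%s\tvectann\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                            cd$chrom, cd$start, cd$end, t$strand, cd$frame, a))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Load a genome FASTA into a sequence store
#'
#' Sequences are uppercased on load. Accessors return `"N"` for positions
#' outside the chromosome so neighborhood extraction at contig edges is
#' total.
#'
#' @param path a FASTA file whose headers match the annotation's chromosome
#'   names (first whitespace-delimited token).
#' @return a `seq_store`.
#' @export
load_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  chrs <- lapply(seq_along(ss), function(i) toupper(as.character(ss[[i]])))
  names(chrs) <- names(ss)
  structure(list(seq = chrs), class = "seq_store")
}

#' @export
print.seq_store <- function(x, ...) {
  cat("<seq_store> ", length(x$seq), " sequences: ",
      paste(sprintf("%s (%d bp)", names(x$seq), nchar(unlist(x$seq))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a 1-based inclusive substring from a sequence store
#'
#' @param store a `seq_store`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates; positions outside the
#'   chromosome are returned as `N`.
#' @return a character scalar of length `end - start + 1`.
#' @export
seq_sub <- function(store, chrom, start, end) {
  s <- store$seq[[chrom]]
  if (is.null(s)) stop("chromosome not in genome: ", chrom)
  n <- nchar(s)
  if (start > end) stop("seq_sub: start > end")
  lo <- max(1L, start)
  hi <- min(n, end)
  core <- if (lo <= hi) substr(s, lo, hi) else ""
  paste0(strrep("N", max(0L, lo - start)), core,
         paste0(strrep("N", max(0L, end - hi))))
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector over \{A,C,G,T,N\}.
#' @return the reverse complement of each element.
#' @examples
#' reverse_complement("ACGTNA")
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
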