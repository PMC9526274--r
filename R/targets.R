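#' Build target regions and the stitched vector coordinate system
#'
#' Target regions are extended coding segments (CDS plus `l_ext` bp on each
#' side, 10 bp by default, to cover splice motifs). The regions are sorted by
#' chromosome, start position, element id (then end and frame as
#' deterministic tie-breaks) and "stitched" into one linear array: position
#' `nu` in `1..l_T` indexes the concatenation of all regions, so one genomic
#' position may map to several `nu` (once per containing region — redundancy
#' across transcripts sharing exons is intended, so that each element is
#' annotated independently).
#'
#' `build_transcript_targets()` emits one region per CDS segment per
#' transcript (per exon with `use_utr = TRUE`); `build_gene_targets()`
#' deduplicates CDS segments within each gene on (start, end, frame) and
#' uses the gene id as the element id.
#'
#' @param model a `gene_model`.
#' @param l_ext extension length in bp (non-negative).
#' @param use_utr use whole exons instead of CDS segments.
#' @return a `target_set`: regions tibble (`chrom`, `start`, `end`,
#'   `element_id`, `source_tx`, `strand`, `frame`, `kind`), cumulative
#'   offsets `cum` (nucleotides before each region), total length `l_T`,
#'   and `l_ext`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 3)
#' ref <- simulate_reference(cfg, dir = tempfile())
#' ts <- build_transcript_targets(load_gene_annotation(ref$gtf), l_ext = 10)
#' glance(ts)
#' @export
build_transcript_targets <- function(model, l_ext = 10, use_utr = FALSE) {
  check_l_ext(l_ext)
  src <- if (use_utr) {
    model$exons |>
      dplyr::mutate(frame = NA_integer_, kind = "exon")
  } else {
    model$cds |> dplyr::mutate(kind = "cds")
  }
  if (nrow(src) == 0) stop("gene model has no target source segments")
  strand_of <- stats::setNames(model$transcripts$strand,
                               model$transcripts$transcript_id)
  regions <- src |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = pmax(1L, .data$start - as.integer(l_ext)),
      end = .data$end + as.integer(l_ext),
      element_id = .data$transcript_id,
      source_tx = .data$transcript_id,
      strand = unname(strand_of[.data$transcript_id]),
      frame = .data$frame,
      kind = .data$kind
    )
  new_target_set(regions, l_ext = l_ext, mode = "transcript")
}

#' @rdname build_transcript_targets
#' @export
build_gene_targets <- function(model, l_ext = 10) {
  check_l_ext(l_ext)
  if (nrow(model$cds) == 0) stop("gene model has no CDS segments")
  info <- model$transcripts |>
    dplyr::select("transcript_id", "gene_id", "strand")
  regions <- model$cds |>
    dplyr::left_join(info, by = "transcript_id") |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$start, .data$end,
                    .data$frame) |>
    dplyr::summarise(source_tx = .data$transcript_id[1],
                     strand = .data$strand[1], .groups = "drop") |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = pmax(1L, .data$start - as.integer(l_ext)),
      end = .data$end + as.integer(l_ext),
      element_id = .data$gene_id,
      source_tx = .data$source_tx,
      strand = .data$strand,
      frame = .data$frame,
      kind = "cds"
    )
  new_target_set(regions, l_ext = l_ext, mode = "gene")
}

check_l_ext <- function(l_ext) {
  if (length(l_ext) != 1 || is.na(l_ext) || l_ext < 0) {
    stop("l_ext must be a single non-negative number")
  }
}

new_target_set <- function(regions, l_ext, mode) {
  regions <- regions |>
    dplyr::mutate(chrom = as.character(.data$chrom)) |>
    dplyr::select("chrom", "start", "end", "element_id", "source_tx",
                  "strand", "frame", "kind") |>
    dplyr::arrange(.data$chrom, .data$start, .data$element_id, .data$end,
                   .data$frame)
  len <- regions$end - regions$start + 1
  structure(
    list(
      regions = regions,
      cum = cumsum(c(0, utils::head(len, -1))),
      ends = cumsum(len),
      l_T = sum(len),
      l_ext = l_ext,
      mode = mode,
      cache = new.env(parent = emptyenv())  # lazy per-chromosome indexes
    ),
    class = "target_set"
  )
}

# per-chromosome region index (IRanges) built once per target set
chrom_index <- function(targets, ch) {
  key <- paste0("ir_", ch)
  if (is.null(targets$cache[[key]])) {
    ri <- which(targets$regions$chrom == ch)
    targets$cache[[key]] <- list(
      ri = ri,
      ir = IRanges::IRanges(targets$regions$start[ri],
                            targets$regions$end[ri])
    )
  }
  targets$cache[[key]]
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", nrow(x$regions), " ", x$mode, "-mode regions, l_T = ",
      x$l_T, " (l_ext = ", x$l_ext, ")\n", sep = "")
  invisible(x)
}

#' A stable content hash of a target set
#'
#' Used by pipeline stages to refuse combining vectors built against
#' different coordinate systems.
#' @param targets a `target_set`.
#' @return an md5 string.
#' @export
target_hash <- function(targets) {
  f <- tempfile()
  on.exit(unlink(f))
  readr::write_tsv(targets$regions, f)
  unname(tools::md5sum(f))
}

#' Map vector coordinates to regions and genomic coordinates
#'
#' `region_index()` finds, for each vector coordinate `nu`, the region whose
#' stitched span contains it (a binary search over cumulative offsets).
#' `vector_to_genomic()` additionally returns the genomic position
#' `start_k + (nu - cum_k - 1)`.
#'
#' @param targets a `target_set`.
#' @param nu vector coordinates in `1..l_T`.
#' @return `region_index()` an integer vector of region indices;
#'   `vector_to_genomic()` a tibble (`nu`, `region`, `chrom`, `pos`,
#'   `element_id`, `strand`).
#' @export
region_index <- function(targets, nu) {
  if (any(nu < 1 | nu > targets$l_T | nu != floor(nu))) {
    stop("coordinate error: nu must be an integer in [1, l_T]")
  }
  findInterval(nu - 1, targets$ends) + 1L
}

#' @rdname region_index
#' @export
vector_to_genomic <- function(targets, nu) {
  k <- region_index(targets, nu)
  r <- targets$regions
  tibble::tibble(
    nu = as.integer(nu),
    region = k,
    chrom = r$chrom[k],
    pos = as.integer(r$start[k] + (nu - targets$cum[k] - 1)),
    element_id = r$element_id[k],
    strand = r$strand[k]
  )
}

#' Map genomic positions to vector coordinates
#'
#' One genomic position maps to `nu = cum_i + (pos - start_i) + 1` for every
#' region i containing it; positions outside all regions map to nothing.
#'
#' @param targets a `target_set`.
#' @param chrom,pos parallel vectors of genomic coordinates.
#' @return a tibble (`chrom`, `pos`, `region`, `nu`), one row per (position,
#'   containing region) pair; zero rows for uncovered positions.
#' @export
genomic_to_vector <- function(targets, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  r <- targets$regions
  out <- vector("list", 0)
  for (ch in unique(chrom)) {
    idx <- chrom_index(targets, ch)
    qi <- which(chrom == ch)
    if (length(idx$ri) == 0 || length(qi) == 0) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos[qi], pos[qi]), idx$ir)
    if (length(hits) == 0) next
    q <- qi[S4Vectors::queryHits(hits)]
    k <- idx$ri[S4Vectors::subjectHits(hits)]
    p <- pos[q]
    out[[length(out) + 1]] <- tibble::tibble(
      chrom = ch,
      pos = p,
      region = k,
      nu = as.integer(targets$cum[k] + (p - r$start[k]) + 1)
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          region = integer(), nu = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$nu)
}

#' Write / read target regions as BED
#'
#' Output is 0-based half-open BED with `element_id|source_tx|frame|kind` in
#' the name column; reading reconstructs a `target_set` (the extension is
#' already baked into the intervals, so `l_ext` is recorded as 0 unless
#' given).
#'
#' @param targets a `target_set`.
#' @param path BED file path.
#' @param l_ext extension length to record on read.
#' @param mode region mode to record on read.
#' @return `write_targets_bed()` returns `path` invisibly;
#'   `read_targets_bed()` a `target_set`.
#' @export
write_targets_bed <- function(targets, path) {
  r <- targets$regions
  writeLines(sprintf("%s\t%d\t%d\t%s|%s|%s|%s\t0\t%s",
                     r$chrom, r$start - 1L, r$end,
                     r$element_id, r$source_tx,
                     ifelse(is.na(r$frame), ".", r$frame), r$kind,
                     r$strand),
             path)
  invisible(path)
}

#' @rdname write_targets_bed
#' @export
read_targets_bed <- function(path, l_ext = 0, mode = "transcript") {
  b <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  parts <- stringr::str_split_fixed(b$name, stringr::fixed("|"), 4)
  regions <- tibble::tibble(
    chrom = b$chrom,
    start = b$start0 + 1L,
    end = b$end,
    element_id = parts[, 1],
    source_tx = parts[, 2],
    frame = suppressWarnings(as.integer(parts[, 3])),
    kind = parts[, 4],
    strand = b$strand
  )
  new_target_set(regions, l_ext = l_ext, mode = mode)
}
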