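#' Parse a VCF into a normalized variant set
#'
#' Multi-allelic rows are split; anchor bases are stripped so that
#' `REF=ACT/ALT=A` at position p becomes the deletion of `p+1..p+2` and
#' `REF=A/ALT=ACT` at p the insertion of `"CT"` after p. Symbolic alleles
#' (`<DEL>`, breakends) are skipped with a warning count; REF/ALT pairs
#' inconsistent with these conventions raise a record-level error naming the
#' offending data line. No left-alignment beyond anchor stripping is
#' performed; inputs are assumed normalized upstream.
#'
#' @param path a VCF 4.x file (sites-only or with genotypes).
#' @return a `variant_set`: tibbles `snvs` (chrom, pos, ref, alt),
#'   `deletions` (chrom, d1, d2 — first/last deleted base, 1-based
#'   inclusive), `insertions` (chrom, pos, seq — inserted after `pos`), and
#'   `n_skipped`.
#' @export
parse_vcf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0) {
    return(new_variant_set(source = path))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop("parse error at line ", body[which(nf < 8)[1]],
         ": expected at least 8 VCF columns")
  }
  chrom <- vapply(fields, `[`, "", 1)
  pos <- as.integer(vapply(fields, `[`, "", 2))
  ref <- toupper(vapply(fields, `[`, "", 4))
  alt_raw <- toupper(vapply(fields, `[`, "", 5))

  snvs <- list(); dels <- list(); inss <- list()
  n_skipped <- 0L
  for (i in seq_along(body)) {
    alts <- strsplit(alt_raw[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (startsWith(alt, "<") || grepl("[", alt, fixed = TRUE) ||
          grepl("]", alt, fixed = TRUE) || alt %in% c("*", ".")) {
        n_skipped <- n_skipped + 1L
        next
      }
      r <- ref[i]; p <- pos[i]
      if (nchar(r) == 1 && nchar(alt) == 1) {
        if (r == alt) {
          stop("record error at line ", body[i], ": ALT equals REF")
        }
        snvs[[length(snvs) + 1]] <- list(chrom = chrom[i], pos = p,
                                         ref = r, alt = alt)
      } else if (nchar(r) > 1 && nchar(alt) == 1) {
        if (substr(r, 1, 1) != alt) {
          stop("record error at line ", body[i],
               ": deletion ALT is not the REF anchor base")
        }
        dels[[length(dels) + 1]] <- list(chrom = chrom[i], d1 = p + 1L,
                                         d2 = p + nchar(r) - 1L)
      } else if (nchar(r) == 1 && nchar(alt) > 1) {
        if (substr(alt, 1, 1) != r) {
          stop("record error at line ", body[i],
               ": insertion ALT does not start with the REF anchor base")
        }
        inss[[length(inss) + 1]] <- list(chrom = chrom[i], pos = p,
                                         seq = substring(alt, 2))
      } else {
        stop("record error at line ", body[i],
             ": REF/ALT pair is neither an SNV nor an anchored indel")
      }
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " symbolic/complex allele(s) skipped")
  }
  new_variant_set(
    snvs = dplyr::bind_rows(snvs),
    deletions = dplyr::bind_rows(dels),
    insertions = dplyr::bind_rows(inss),
    n_skipped = n_skipped, source = path
  )
}

new_variant_set <- function(snvs = NULL, deletions = NULL, insertions = NULL,
                            n_skipped = 0L, source = NA_character_) {
  empty <- function(x, proto) if (is.null(x) || nrow(x) == 0) proto else x
  structure(
    list(
      snvs = empty(snvs, tibble::tibble(chrom = character(), pos = integer(),
                                        ref = character(), alt = character())),
      deletions = empty(deletions, tibble::tibble(chrom = character(),
                                                  d1 = integer(), d2 = integer())),
      insertions = empty(insertions, tibble::tibble(chrom = character(),
                                                    pos = integer(),
                                                    seq = character())),
      n_skipped = n_skipped,
      source = source
    ),
    class = "variant_set"
  )
}

#' Assemble a variant set from tibbles
#'
#' Programmatic constructor mirroring [parse_vcf()]'s output, used by the
#' simulator and in tests.
#' @param snvs tibble (chrom, pos, ref, alt).
#' @param deletions tibble (chrom, d1, d2).
#' @param insertions tibble (chrom, pos, seq).
#' @return a `variant_set`.
#' @export
variant_set <- function(snvs = NULL, deletions = NULL, insertions = NULL) {
  vs <- new_variant_set(snvs, deletions, insertions)
  stopifnot(all(vs$deletions$d1 <= vs$deletions$d2),
            all(nchar(vs$insertions$seq) > 0))
  vs
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", nrow(x$snvs), " SNVs, ", nrow(x$deletions),
      " deletions, ", nrow(x$insertions), " insertions",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " skipped)"), "\n",
      sep = "")
  invisible(x)
}

#' Encode variants as a binary loci vector
#'
#' For SNV alleles, every vector coordinate that a variant position maps to
#' is set to 1 (one bit per containing region). Deletions set every position
#' of their span (the 1-bp-deletion state representation); insertions set the
#' position after which the insertion occurs. Variants mapping to no target
#' contribute nothing and are counted in `n_off_target`.
#'
#' @param vs a `variant_set`.
#' @param targets a `target_set`.
#' @param allele one of [point_alleles()] (`"d"` deletion state, `"i"`
#'   insertion state).
#' @return a `loci_vector`: binary `bits` of length `l_T`, the allele, the
#'   target hash and the off-target variant count.
#' @export
vectorize_loci <- function(vs, targets, allele) {
  stopifnot(inherits(vs, "variant_set"), allele %in% point_alleles())
  bits <- integer(targets$l_T)
  n_var <- 0L
  n_hit <- 0L
  if (allele %in% c("A", "C", "G", "T")) {
    v <- vs$snvs[vs$snvs$alt == allele, ]
    n_var <- nrow(v)
    if (n_var > 0) {
      m <- genomic_to_vector(targets, v$chrom, v$pos)
      bits[m$nu] <- 1L
      n_hit <- length(unique(paste(m$chrom, m$pos)))
    }
  } else if (allele == "d") {
    v <- vs$deletions
    n_var <- nrow(v)
    if (n_var > 0) {
      pos <- unlist(lapply(seq_len(nrow(v)), function(i) v$d1[i]:v$d2[i]))
      ch <- rep(v$chrom, v$d2 - v$d1 + 1)
      m <- genomic_to_vector(targets, ch, pos)
      bits[m$nu] <- 1L
      # a deletion is on-target if any of its bases maps
      covered <- unique(paste(m$chrom, m$pos))
      n_hit <- sum(vapply(seq_len(nrow(v)), function(i) {
        any(paste(v$chrom[i], v$d1[i]:v$d2[i]) %in% covered)
      }, logical(1)))
    }
  } else {
    v <- vs$insertions
    n_var <- nrow(v)
    if (n_var > 0) {
      m <- genomic_to_vector(targets, v$chrom, v$pos)
      bits[m$nu] <- 1L
      n_hit <- length(unique(paste(m$chrom, m$pos)))
    }
  }
  structure(
    list(allele = allele, bits = bits, l_T = targets$l_T,
         target_hash = target_hash(targets),
         n_variants = n_var, n_off_target = n_var - n_hit),
    class = "loci_vector"
  )
}

#' @export
print.loci_vector <- function(x, ...) {
  cat("<loci_vector> allele ", x$allele, ", ", sum(x$bits), " of ", x$l_T,
      " positions set (", x$n_off_target, " off-target variants)\n", sep = "")
  invisible(x)
}

#' Encrypt a loci vector
#'
#' Client-side step: the binary loci vector is chunked and encrypted under
#' the researcher's public key; the allele and target-set hash ride along as
#' public metadata so the server can refuse mismatched coordinate systems.
#'
#' @param loci a `loci_vector`.
#' @param pk the researcher's `he_public_key`.
#' @param slot slot bound (see [he_encrypt()]).
#' @return a `cipher_vector`.
#' @export
encrypt_loci <- function(loci, pk, slot = 32768) {
  he_encrypt(loci$bits, pk, slot = slot,
             meta = list(allele = loci$allele,
                         target_hash = loci$target_hash))
}

# parse GT strings ("0/1", "1|1", "./.") into alt-dosages for alt index 1
gt_dosage <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  bad <- lengths(parts) != 2
  if (any(bad)) stop("ploidy error: genotypes must be diploid (", gt[bad][1], ")")
  a <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  miss <- a[, 1] == "." | a[, 2] == "."
  d <- (a[, 1] == "1") + (a[, 2] == "1")
  d[miss] <- 0L
  list(dosage = as.integer(d), missing = miss)
}

#' Encode per-sample genotypes on the vector coordinates
#'
#' Builds the `l_T x n_G` genotype matrix for one allele. In `dosage` mode an
#' entry is the number of alternate alleles (0/1/2); in `existence` mode it
#' flags presence (0/1, the 2-level encoding used for beacon-style counts and
#' required by the deletion-span statistic). Deletions expand to their
#' spanned positions per sample; deletions not fully contained in a target
#' region ("not engulfed") are excluded from the deletion-state matrix, so
#' the exact-span statistic only ever sees complete spans. Missing genotypes
#' (`./.`) encode as 0 and are tallied per sample.
#'
#' @param path a multi-sample VCF with GT fields (all samples share the site
#'   list).
#' @param targets a `target_set`.
#' @param allele one of [point_alleles()].
#' @param mode `"dosage"` or `"existence"`.
#' @return a `genotype_matrix`: integer `values` (`l_T x n_G`), sample names,
#'   mode, allele, per-sample missing counts and the target hash.
#' @export
vectorize_genotypes <- function(path, targets, allele, mode = c("dosage", "existence")) {
  mode <- match.arg(mode)
  stopifnot(allele %in% point_alleles())
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stop("VCF has no #CHROM header line")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)

  n_G <- length(samples)
  values <- matrix(0L, nrow = targets$l_T, ncol = n_G)
  missing <- integer(n_G)

  for (f in fields) {
    chrom <- f[1]; pos <- as.integer(f[2])
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multi-sample encoding expects biallelic rows; split upstream")
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- which(fmt == "GT")
    if (length(gti) != 1) stop("row without GT field at ", chrom, ":", pos)
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gti)
    dd <- gt_dosage(gt)
    missing <- missing + dd$missing
    dos <- dd$dosage
    if (mode == "existence") dos <- as.integer(dos > 0)
    if (all(dos == 0)) next

    type <- if (nchar(ref) == 1 && nchar(alt) == 1) "snv"
            else if (nchar(ref) > 1 && nchar(alt) == 1) "del"
            else "ins"
    hit_allele <- switch(type, snv = alt, del = "d", ins = "i")
    if (hit_allele != allele) next

    if (type == "del") {
      d1 <- pos + 1L; d2 <- pos + nchar(ref) - 1L
      # engulfed check: every deleted base must map within a single region
      m <- genomic_to_vector(targets, rep(chrom, d2 - d1 + 1), d1:d2)
      if (nrow(m) == 0) next
      for (k in unique(m$region)) {
        mk <- m[m$region == k, ]
        if (nrow(mk) < (d2 - d1 + 1)) next  # not engulfed in this region
        for (s in which(dos > 0)) {
          values[mk$nu, s] <- pmin(values[mk$nu, s] + dos[s],
                                   if (mode == "existence") 1L else 2L)
        }
      }
    } else {
      p <- if (type == "ins") pos else pos
      m <- genomic_to_vector(targets, chrom, p)
      if (nrow(m) == 0) next
      nz <- which(dos > 0)
      for (s in nz) values[m$nu, s] <- dos[s]
    }
  }

  len <- targets$ends - targets$cum
  structure(
    list(allele = allele, mode = mode, values = values, n_G = n_G,
         samples = samples, missing = missing,
         region = rep.int(seq_along(len), len),  # region id per slot
         target_hash = target_hash(targets)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> allele ", x$allele, ", ", nrow(x$values), " x ",
      x$n_G, " (", x$mode, " encoding)\n", sep = "")
  invisible(x)
}

#' Element-level vectorization of non-coding variants
#'
#' Coarse representation for non-coding and regulatory elements: one entry
#' per element, set to 1 when any variant overlaps the element (a single
#' overlap operation, not per-nucleotide).
#'
#' @param vs a `variant_set`.
#' @param elements a tibble (`name`, `chrom`, `start`, `end`), sorted.
#' @return the input tibble plus a binary `value` column.
#' @export
vectorize_noncoding_elements <- function(vs, elements) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(elements)))
  spans <- dplyr::bind_rows(
    vs$snvs |> dplyr::transmute(chrom = .data$chrom, s = .data$pos, e = .data$pos),
    vs$deletions |> dplyr::transmute(chrom = .data$chrom, s = .data$d1, e = .data$d2),
    vs$insertions |> dplyr::transmute(chrom = .data$chrom, s = .data$pos, e = .data$pos)
  )
  value <- integer(nrow(elements))
  for (ch in unique(elements$chrom)) {
    ei <- which(elements$chrom == ch)
    vi <- which(spans$chrom == ch)
    if (length(ei) == 0 || length(vi) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(elements$start[ei], elements$end[ei]),
      IRanges::IRanges(spans$s[vi], spans$e[vi])
    )
    value[ei[unique(S4Vectors::queryHits(hits))]] <- 1L
  }
  dplyr::mutate(elements, value = value)
}

#' Write a sites-only or multi-sample VCF
#'
#' @param variants tibble with columns `chrom`, `pos`, `ref`, `alt` (VCF
#'   conventions, anchor bases included).
#' @param path output path.
#' @param gt optional character matrix of GT strings (rows = variants,
#'   columns = samples, with column names).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, gt = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=vectann")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) {
    hdr <- c(hdr, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    cols <- c(cols, "FORMAT", colnames(gt))
  }
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  variants$chrom, variants$pos, variants$ref, variants$alt)
  if (!is.null(gt)) {
    rows <- paste(rows, "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}
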