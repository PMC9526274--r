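#' Aggregate allele counts over a genotype matrix
#'
#' The frequency vector is the slot-wise sum of the genotype matrix over
#' samples: in dosage mode the aggregate is the allele count (AC) at each
#' vector position; in existence mode it is the number of carriers
#' (beacon-style). Counts are returned raw — allele frequency is a
#' presentation-layer division by 2 n_G (or n_G), keeping everything integer
#' under encryption.
#'
#' @param G a `genotype_matrix`.
#' @return a `frequency_vector`: `counts` (length `l_T`), allele, mode,
#'   `n_G`, source count `M`, and the target hash.
#' @export
aggregate_snv <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  new_frequency_vector(rowSums(G$values), G)
}

#' @rdname aggregate_snv
#' @export
insertion_position_frequency <- function(G) {
  # the position of an insertion aggregates like an SNV; inserted-sequence
  # identity is deliberately not distinguished
  stopifnot(G$allele == "i")
  aggregate_snv(G)
}

new_frequency_vector <- function(counts, G, M = 1L, span = NA_integer_) {
  structure(
    list(allele = G$allele, mode = G$mode, counts = as.double(counts),
         n_G = G$n_G, M = M, span = span, target_hash = G$target_hash),
    class = "frequency_vector"
  )
}

#' @export
print.frequency_vector <- function(x, ...) {
  cat("<frequency_vector> allele ", x$allele,
      if (!is.na(x$span)) paste0(" (span ", x$span, ")"),
      ", n_G = ", x$n_G, " over ", x$M, " source(s), ",
      sum(x$counts > 0), " non-zero positions\n", sep = "")
  invisible(x)
}

#' Exact-span deletion-length aggregation
#'
#' Counts, per vector position, the samples whose 1-bp deletion state is 1 on
#' the whole window `[nu, nu + l_delta]` and 0 at both flanks
#' (`nu - 1` and `nu + l_delta + 1`), i.e. deletions spanning exactly that
#' window. Flanks outside the vector or outside the containing target region
#' count as 0, and windows crossing a region boundary are invalid, so only
#' deletions engulfed in a region are aggregated. Note the window covers
#' `l_delta + 1` positions — the formula's index convention; use
#' [aggregate_deletion_span()] to pass the deleted-base count directly.
#'
#' @param G a `genotype_matrix` for allele `d` in existence encoding.
#' @param l_delta window parameter (window = `l_delta + 1` deleted bases).
#' @param n_bases deleted-base count (`= l_delta + 1`).
#' @return a `frequency_vector` whose `span` field records the deleted-base
#'   count.
#' @export
aggregate_deletion_length <- function(G, l_delta) {
  stopifnot(inherits(G, "genotype_matrix"), l_delta >= 0)
  if (G$mode != "existence") {
    stop("encoding error: the deletion-span statistic needs existence encoding")
  }
  n <- nrow(G$values)
  reg <- G$region
  shift_vec <- function(x, k) {
    # value of slot i + k, zero-filled (mirrors he_shift)
    if (k == 0) return(x)
    out <- rep(0L, n)
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    out[ok] <- x[src[ok]]
    out
  }
  same_region <- function(k) {
    # TRUE where slot i + k exists and lies in the same region as slot i
    idx <- seq_len(n) + k
    ok <- idx >= 1 & idx <= n
    ok[ok] <- reg[idx[ok]] == reg[seq_len(n)][ok]
    ok
  }
  span_ok <- same_region(l_delta)
  m_left <- same_region(-1)
  m_right <- same_region(l_delta + 1)

  counts <- numeric(n)
  for (k in seq_len(ncol(G$values))) {
    x <- G$values[, k]
    ind <- rep(TRUE, n)
    for (l in 0:l_delta) ind <- ind & (shift_vec(x, l) == 1L)
    left <- shift_vec(x, -1) * m_left
    right <- shift_vec(x, l_delta + 1) * m_right
    counts <- counts + (ind & span_ok & left == 0 & right == 0)
  }
  new_frequency_vector(counts, G, span = l_delta + 1L)
}

#' @rdname aggregate_deletion_length
#' @export
aggregate_deletion_span <- function(G, n_bases) {
  stopifnot(n_bases >= 1)
  aggregate_deletion_length(G, n_bases - 1L)
}

#' Encrypt a genotype matrix column-by-column
#'
#' Each sample's slot vector is chunked and encrypted separately (the
#' row-major SIMD layout), so aggregation is a ciphertext sum.
#'
#' @param G a `genotype_matrix`.
#' @param pk the owner's `he_public_key`.
#' @param slot slot bound.
#' @return a list of `cipher_vector`s, one per sample.
#' @export
encrypt_genotypes <- function(G, pk, slot = 32768) {
  meta <- list(allele = G$allele, mode = G$mode, target_hash = G$target_hash)
  lapply(seq_len(ncol(G$values)), function(k) {
    he_encrypt(G$values[, k], pk, slot = slot, meta = meta)
  })
}

#' Aggregate encrypted genotype columns
#'
#' @param cols list of `cipher_vector`s under one key.
#' @return a `cipher_vector` holding the slot-wise sum.
#' @export
aggregate_encrypted <- function(cols) {
  stopifnot(length(cols) >= 1)
  Reduce(he_add, cols)
}

#' Exact-span deletion aggregation under encryption
#'
#' Evaluates the same indicator as [aggregate_deletion_length()] with
#' ciphertext arithmetic: per sample, the product of the `l_delta + 1`
#' shifted copies of the deletion-state vector and of `1 - flank` terms
#' (flanks masked by the public region geometry), then the sum over samples.
#' Multiplication depth is `l_delta + 3`.
#'
#' @param cols list of `cipher_vector`s (existence-encoded deletion states),
#'   one per sample, under one key.
#' @param l_delta window parameter, as in [aggregate_deletion_length()].
#' @param region integer vector: region id of each slot (public coordinate
#'   geometry, e.g. `genotype_matrix$region`).
#' @return a `cipher_vector` decrypting to the exact-span counts.
#' @export
aggregate_deletion_length_encrypted <- function(cols, l_delta, region) {
  stopifnot(length(cols) >= 1, l_delta >= 0)
  n <- cols[[1]]$len
  stopifnot(length(region) == n)
  same_region <- function(k) {
    idx <- seq_len(n) + k
    ok <- idx >= 1 & idx <= n
    ok[ok] <- region[idx[ok]] == region[seq_len(n)][ok]
    as.numeric(ok)
  }
  span_ok <- same_region(l_delta)
  m_left <- same_region(-1)
  m_right <- same_region(l_delta + 1)

  total <- NULL
  for (cv in cols) {
    ind <- cv
    if (l_delta > 0) {
      for (l in 1:l_delta) ind <- he_mul(ind, he_shift(cv, l))
    }
    left <- he_mul_plain(he_shift(cv, -1), m_left)
    right <- he_mul_plain(he_shift(cv, l_delta + 1), m_right)
    one_minus_left <- he_add_plain(he_mul_plain(left, -1), 1)
    one_minus_right <- he_add_plain(he_mul_plain(right, -1), 1)
    indicator <- he_mul_plain(he_mul(he_mul(ind, one_minus_left),
                                     one_minus_right), span_ok)
    total <- if (is.null(total)) indicator else he_add(total, indicator)
  }
  total
}

#' Pool encrypted genotype sources via key switching
#'
#' The federated aggregation protocol: each source's encrypted columns are
#' summed under the owner's key, re-encrypted to the researcher's key with
#' the source's switching key, and the switched aggregates are summed. Every
#' switching key is checked against its source's key tag before any
#' arithmetic. The result decrypts, under the researcher's secret key, to
#' the element-wise sum of all sources' plaintext aggregates.
#'
#' @param sources list of sources; each is a list of `cipher_vector` columns
#'   under that owner's key.
#' @param switch_keys list of `switch_key`s, one per source, all targeting
#'   the researcher's key.
#' @return a `cipher_vector` under the researcher's key.
#' @export
pool_and_aggregate <- function(sources, switch_keys) {
  stopifnot(length(sources) == length(switch_keys), length(sources) >= 1)
  to_keys <- unique(vapply(switch_keys, function(s) s$to, character(1)))
  if (length(to_keys) != 1) {
    stop("key error: switching keys target different researcher keys")
  }
  for (m in seq_along(sources)) {
    kid <- unique(vapply(sources[[m]], function(cv) cv$key_id, character(1)))
    if (length(kid) != 1 || kid != switch_keys[[m]]$from) {
      stop("key error: source ", m, " is not covered by its switching key")
    }
  }
  switched <- lapply(seq_along(sources), function(m) {
    key_switch(aggregate_encrypted(sources[[m]]), switch_keys[[m]])
  })
  Reduce(he_add, switched)
}

#' Frequency output as a tidy table
#'
#' @param x a `frequency_vector`.
#' @param targets the matching `target_set` (for genomic coordinates).
#' @param keep_zero keep zero-count positions.
#' @param ... unused.
#' @return a tibble (`nu`, `chrom`, `pos`, `element_id`, `allele`, `count`,
#'   `n_G`, `af`).
#' @export
tidy.frequency_vector <- function(x, targets = NULL, keep_zero = FALSE, ...) {
  nu <- if (keep_zero) seq_along(x$counts) else which(x$counts > 0)
  denom <- if (x$mode == "dosage") 2 * x$n_G else x$n_G
  base <- tibble::tibble(nu = as.integer(nu), allele = x$allele,
                         count = x$counts[nu], n_G = x$n_G,
                         af = x$counts[nu] / denom)
  if (is.null(targets)) return(base)
  stopifnot(identical(target_hash(targets), x$target_hash))
  g <- vector_to_genomic(targets, base$nu)
  dplyr::bind_cols(g[, c("chrom", "pos", "element_id")], base) |>
    dplyr::relocate("nu")
}

#' Write a frequency vector as TSV
#'
#' @param x a `frequency_vector`.
#' @param targets the matching `target_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(x, targets, path) {
  readr::write_tsv(tidy.frequency_vector(x, targets), path)
  invisible(path)
}
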