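#' Encode a 6-nucleotide neighborhood as an 18-bit integer
#'
#' Each base gets a 3-bit code (A: 000, C: 001, G: 010, T: 011, N: 100);
#' the leftmost base occupies the most significant 3-bit group, so a
#' 6-base neighborhood fits in 18 bits. Neighborhoods are always stored in
#' genomic plus-strand orientation; reverse complementation for minus-strand
#' elements happens at translation time.
#'
#' @param seq character vector of 6-character strings over \{A,C,G,T,N\}.
#' @param code integer vector of 18-bit neighborhood codes.
#' @return `encode_neighborhood()` an integer vector; `decode_neighborhood()`
#'   a character vector of 6-mers.
#' @examples
#' encode_neighborhood("ACGTNA")
#' decode_neighborhood(encode_neighborhood("TTTTTT"))
#' @export
encode_neighborhood <- function(seq) {
  if (any(nchar(seq) != 6)) stop("neighborhood must be exactly 6 nucleotides")
  m <- matrix(match(unlist(strsplit(seq, "", fixed = TRUE)),
                    c("A", "C", "G", "T", "N")) - 1L,
              nrow = 6)
  if (anyNA(m)) stop("neighborhood alphabet is {A,C,G,T,N}")
  as.integer(colSums(m * 8L^(5:0)))
}

#' @rdname encode_neighborhood
#' @export
decode_neighborhood <- function(code) {
  stopifnot(all(code >= 0), all(code < 2^18))
  vapply(as.integer(code), function(v) {
    digits <- (v %/% 8L^(5:0)) %% 8L
    paste(c("A", "C", "G", "T", "N")[digits + 1L], collapse = "")
  }, character(1))
}

#' Pack and unpack 58-bit impact values
#'
#' A packed impact value is
#' `(((bitmap << 18) + neighborhood) << 2) + frame`: a 38-bit consequence
#' bitmap, an 18-bit 6-nucleotide neighborhood, and a 2-bit coding frame,
#' stored in a 64-bit slot (see [as_i64()]). `pack_impact()` is vectorized
#' over its three arguments.
#'
#' @param frame coding frame, in \{0,1,2\} (0 for non-coding positions).
#' @param neighborhood 18-bit neighborhood codes (see
#'   [encode_neighborhood()]) or 6-character strings.
#' @param bitmap 38-bit consequence bitmaps (see [terms_to_bitmap()]).
#' @param packed an `i64` vector of packed values.
#' @return `pack_impact()` an `i64` vector; `unpack_impact()` a tibble with
#'   columns `frame`, `neighborhood` (decoded 6-mer), `neighborhood_code`
#'   and `bitmap`.
#' @examples
#' p <- pack_impact(2, "AAAAAC", terms_to_bitmap("intron_variant"))
#' unpack_impact(p)
#' @export
pack_impact <- function(frame, neighborhood, bitmap) {
  if (is.character(neighborhood)) neighborhood <- encode_neighborhood(neighborhood)
  n <- max(length(frame), length(neighborhood), length(bitmap))
  .i64_pack_impact(rep_len(as.integer(frame), n),
                   rep_len(as.integer(neighborhood), n),
                   rep_len(as.double(bitmap), n))
}

#' @rdname pack_impact
#' @export
unpack_impact <- function(packed) {
  u <- .i64_unpack_impact(as_i64(packed))
  tibble::tibble(
    frame = u$frame,
    neighborhood = decode_neighborhood(u$neighborhood),
    neighborhood_code = u$neighborhood,
    bitmap = u$bitmap
  )
}
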