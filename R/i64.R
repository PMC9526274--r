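#' Exact 64-bit integer vectors
#'
#' Packed impact values occupy up to 58 bits, beyond the 53-bit exact range of
#' a double, so the package carries a minimal integer-64 vector class. Values
#' are stored as the raw bit patterns of `int64_t` inside a numeric vector
#' (the `bit64` trick); all arithmetic happens in compiled code and is exact.
#' Subsetting and concatenation are bit-pattern-preserving, but ordinary
#' numeric arithmetic on an `i64` is an error by construction.
#'
#' @param x a numeric vector of integral values with absolute value below
#'   2^53 (exactly representable), or an existing `i64`.
#' @return an `i64` vector.
#' @examples
#' v <- as_i64(c(0, 1, 2))
#' as.double(v + as_i64(c(5, 5, 5)))
#' @export
as_i64 <- function(x) {
  if (is_i64(x)) return(x)
  .i64_from_double(as.double(x))
}

#' @rdname as_i64
#' @export
is_i64 <- function(x) inherits(x, "i64")

#' @export
as.double.i64 <- function(x, ...) .i64_to_double(x)

#' @exportS3Method base::format
format.i64 <- function(x, ...) .i64_format(x)

#' @export
print.i64 <- function(x, ...) {
  cat("<i64[", length(x), "]>\n", sep = "")
  print(format(x))
  invisible(x)
}

#' @export
`[.i64` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "i64"
  out
}

#' @export
c.i64 <- function(...) {
  parts <- lapply(list(...), function(p) unclass(as_i64(p)))
  out <- do.call(c, parts)
  class(out) <- "i64"
  out
}

#' @export
`+.i64` <- function(e1, e2) .i64_add(as_i64(e1), as_i64(e2))

#' @export
`*.i64` <- function(e1, e2) .i64_mul(as_i64(e1), as_i64(e2))

#' @export
`==.i64` <- function(e1, e2) .i64_eq(as_i64(e1), as_i64(e2))

#' @export
length.i64 <- function(x) length(unclass(x))

#' Zero-filled i64 vector
#' @param n length.
#' @return an `i64` vector of `n` zeros.
#' @export
i64_zeros <- function(n) .i64_zeros(as.double(n))

#' Indices of non-zero entries of an i64 vector
#' @param x an `i64` vector.
#' @return integer indices (1-based).
#' @export
i64_nonzero <- function(x) .i64_nonzero(as_i64(x))

# max |value| as a double (range checks only; exact below 2^53, close enough
# above it since the hard 2^62 bound is enforced in compiled code anyway)
i64_max_abs <- function(x) .i64_max_abs(as_i64(x))
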