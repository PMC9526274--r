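#' The secure-compute backend contract (plaintext mock)
#'
#' The pipeline's cryptographic layer is specified as a contract: SIMD-style
#' slot vectors of at most `slot` values per ciphertext, slot-wise addition
#' and multiplication, plaintext-constant operations, slot rotation, and key
#' switching (proxy re-encryption). The package ships a bit-exact plaintext
#' mock of this contract: ciphertexts store their values (as exact [as_i64()]
#' integers) together with a key-id tag, and every operation refuses
#' mismatched keys, so protocol errors are testable without any cryptography.
#' Server-side operations never take a secret key — only public material —
#' which makes the trust boundary visible in the API itself.
#'
#' @details `keygen()` returns a keypair whose `$public` and `$secret` parts
#' carry the same unique key id. `gen_switch_key()` is performed by the key
#' manager (it needs both secret keys) and produces a directional switching
#' key usable only on ciphertexts under its `from` key.
#'
#' The headroom contract: the mock represents slot values exactly up to
#' [he_slot_capacity()] (2^62); `he_encrypt()` refuses anything larger, so
#' callers must keep packed impact values (< 2^58) and aggregate counts
#' within bounds.
#'
#' @param label optional human-readable label for the key.
#' @return `keygen()` an `he_keypair`.
#' @examples
#' kp <- keygen()
#' cv <- he_encrypt(c(1, 2, 3), kp$public, slot = 2)
#' as.double(he_decrypt(cv, kp$secret))
#' @export
keygen <- function(label = NULL) {
  n <- .key_counter$n <- .key_counter$n + 1L
  id <- sprintf("key-%04d%s", n, if (is.null(label)) "" else paste0("-", label))
  structure(
    list(
      key_id = id,
      public = structure(list(key_id = id), class = "he_public_key"),
      secret = structure(list(key_id = id), class = "he_secret_key")
    ),
    class = "he_keypair"
  )
}

.key_counter <- new.env(parent = emptyenv())
.key_counter$n <- 0L

#' @rdname keygen
#' @param sk_from,sk_to secret keys (key-manager role).
#' @return `gen_switch_key()` a `switch_key` converting `from`-ciphertexts
#'   to `to`-ciphertexts.
#' @export
gen_switch_key <- function(sk_from, sk_to) {
  stopifnot(inherits(sk_from, "he_secret_key"), inherits(sk_to, "he_secret_key"))
  structure(list(from = sk_from$key_id, to = sk_to$key_id),
            class = "switch_key")
}

#' @rdname keygen
#' @return `he_slot_capacity()` the largest slot value the backend
#'   represents exactly.
#' @export
he_slot_capacity <- function() 2^62

#' Encrypt and decrypt slot vectors
#'
#' A logical vector of length `n` is split into `ceiling(n / slot)` chunks of
#' at most `slot` values (only the last chunk may be short), each chunk
#' standing for one ciphertext.
#'
#' @param values numeric or `i64` vector of exact integers, all below
#'   [he_slot_capacity()].
#' @param pk an `he_public_key`.
#' @param slot the slot bound `l` (maximum plaintext vector length per
#'   ciphertext); default 32768.
#' @param meta optional named list carried on the ciphertext (e.g. allele and
#'   target-set hash for pipeline consistency checks).
#' @return `he_encrypt()` a `cipher_vector`; `he_decrypt()` the exact `i64`
#'   plaintext.
#' @export
he_encrypt <- function(values, pk, slot = 32768, meta = list()) {
  stopifnot(inherits(pk, "he_public_key"), slot >= 1)
  v <- as_i64(values)
  n <- length(v)
  if (n == 0) stop("cannot encrypt an empty vector")
  if (i64_max_abs(v) >= he_slot_capacity()) {
    stop("headroom contract violated: slot value exceeds backend capacity")
  }
  starts <- seq.int(1L, n, by = slot)
  chunks <- lapply(starts, function(s) v[s:min(n, s + slot - 1L)])
  structure(list(chunks = chunks, key_id = pk$key_id, slot = slot,
                 len = n, meta = meta),
            class = "cipher_vector")
}

#' @rdname he_encrypt
#' @param cv a `cipher_vector`.
#' @param sk the matching `he_secret_key`.
#' @export
he_decrypt <- function(cv, sk) {
  stopifnot(inherits(cv, "cipher_vector"), inherits(sk, "he_secret_key"))
  if (sk$key_id != cv$key_id) {
    stop("decryption error: ciphertext is under key ", cv$key_id,
         ", not ", sk$key_id)
  }
  cv_values(cv)
}

cv_values <- function(cv) do.call(c, cv$chunks)

#' @export
print.cipher_vector <- function(x, ...) {
  cat("<cipher_vector> ", length(x$chunks), " chunk(s), ", x$len,
      " slots (l = ", x$slot, "), key ", x$key_id, "\n", sep = "")
  invisible(x)
}

#' Number of ciphertext chunks
#' @param cv a `cipher_vector`.
#' @return integer chunk count, `ceiling(len / slot)`.
#' @export
n_chunks <- function(cv) length(cv$chunks)

rebuild_cv <- function(cv, values) {
  n <- length(values)
  starts <- seq.int(1L, n, by = cv$slot)
  cv$chunks <- lapply(starts, function(s) values[s:min(n, s + cv$slot - 1L)])
  cv$len <- n
  cv
}

check_pair <- function(a, b) {
  if (a$key_id != b$key_id) {
    stop("key error: operands are under different keys (", a$key_id,
         " vs ", b$key_id, ")")
  }
  if (a$len != b$len) stop("shape error: slot lengths differ")
}

#' Homomorphic slot-wise arithmetic (mock backend)
#'
#' Slot-wise operations under encryption: ciphertext-ciphertext addition and
#' multiplication, plaintext-constant multiplication and addition, and slot
#' shifts. All are exact integer arithmetic in the mock; key and shape are
#' checked before any work.
#'
#' @param a,b `cipher_vector`s under the same key with equal logical length.
#' @return a `cipher_vector` under the same key.
#' @export
he_add <- function(a, b) {
  check_pair(a, b)
  rebuild_cv(a, cv_values(a) + cv_values(b))
}

#' @rdname he_add
#' @export
he_mul <- function(a, b) {
  check_pair(a, b)
  rebuild_cv(a, cv_values(a) * cv_values(b))
}

#' @rdname he_add
#' @param cv a `cipher_vector`.
#' @param plain a plaintext numeric or `i64` vector of the same logical
#'   length (recycled if scalar).
#' @export
he_mul_plain <- function(cv, plain) {
  p <- as_i64(rep_len(if (is_i64(plain)) as.double(plain) else plain, cv$len))
  rebuild_cv(cv, cv_values(cv) * p)
}

#' @rdname he_add
#' @export
he_add_plain <- function(cv, plain) {
  p <- as_i64(rep_len(if (is_i64(plain)) as.double(plain) else plain, cv$len))
  rebuild_cv(cv, cv_values(cv) + p)
}

#' @rdname he_add
#' @param k shift offset: `he_shift(cv, k)` puts the value of slot `i + k`
#'   into slot `i` (zero fill at the edges), the standard SIMD rotation-
#'   with-mask primitive.
#' @export
he_shift <- function(cv, k) {
  v <- as.double(rep(0, cv$len))
  src <- seq_len(cv$len) + k
  ok <- src >= 1 & src <= cv$len
  out <- as_i64(v)
  vals <- cv_values(cv)
  out <- unclass(out)
  out[which(ok)] <- unclass(vals)[src[ok]]
  class(out) <- "i64"
  rebuild_cv(cv, out)
}

#' Key switching (proxy re-encryption)
#'
#' Converts a ciphertext under the switching key's `from` key into one
#' decryptable under its `to` key, without decryption. The mock enforces the
#' directional contract: the key tag must match `swk$from` exactly.
#'
#' @param cv a `cipher_vector`.
#' @param swk a `switch_key` with `swk$from == cv$key_id`.
#' @return the re-encrypted `cipher_vector` (chunk structure unchanged).
#' @export
key_switch <- function(cv, swk) {
  stopifnot(inherits(cv, "cipher_vector"), inherits(swk, "switch_key"))
  if (cv$key_id != swk$from) {
    stop("key error: switch key converts ", swk$from, " -> ", swk$to,
         " but ciphertext is under ", cv$key_id)
  }
  cv$key_id <- swk$to
  cv
}

#' Serialize a cipher vector to disk
#'
#' One directory per cipher: a JSON manifest (key id, slot bound, logical
#' length, chunk count, metadata) plus one decimal-text blob per chunk.
#'
#' @param cv a `cipher_vector`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cipher <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(key_id = cv$key_id, slot = cv$slot, len = cv$len,
                   n_chunks = length(cv$chunks), meta = cv$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  for (j in seq_along(cv$chunks)) {
    writeLines(format(cv$chunks[[j]]),
               file.path(dir, sprintf("chunk-%05d.txt", j)))
  }
  invisible(dir)
}

#' @rdname write_cipher
#' @export
read_cipher <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  chunks <- lapply(seq_len(manifest$n_chunks), function(j) {
    .i64_from_string(readLines(file.path(dir, sprintf("chunk-%05d.txt", j))))
  })
  structure(list(chunks = chunks, key_id = manifest$key_id,
                 slot = manifest$slot, len = manifest$len,
                 meta = as.list(manifest$meta)),
            class = "cipher_vector")
}
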