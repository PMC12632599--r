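# GA4GH digest primitive: SHA-512 truncated to 24 bytes, base64url.

#' GA4GH truncated SHA-512 digest (sha512t24u)
#'
#' Computes the digest used throughout the refget standards: SHA-512 of the
#' input bytes, truncated to its first 24 bytes and encoded with the
#' base64url alphabet (RFC 4648 section 5) without padding.  The result is
#' always exactly 32 characters drawn from `[A-Za-z0-9_-]`.
#'
#' @param data A raw vector, or a character scalar which is digested as its
#'   UTF-8 bytes.  Empty input is allowed.
#' @return A 32-character digest string.
#' @examples
#' sha512t24u("")      # "z4PhNX7vuL3xVChQ1m2AB9Yg5AULVxXc"
#' sha512t24u("ACGT")
#' @export
sha512t24u <- function(data) {
  if (is.character(data)) {
    stopifnot(length(data) == 1L, !is.na(data))
    data <- charToRaw(enc2utf8(data))
  }
  if (!is.raw(data)) stop("`data` must be a raw vector or character scalar")
  h <- openssl::sha512(data)
  jsonlite::base64url_enc(h[1:24])
}

#' Content-derived digest of a single sequence
#'
#' Digests the residues of one sequence after uppercasing, following the
#' refget Sequences convention.  Soft-masked (lowercase) and unmasked copies
#' of the same residues therefore share a digest, while hard-masking
#' (replacing residues with `N`) changes it.  Residues are digested as
#' bytes; no normalization beyond case folding is applied.
#'
#' @param sequence Character scalar of residue characters, no whitespace.
#'   The empty string is allowed and digests the empty byte string.
#' @return A 32-character digest string.
#' @examples
#' sequence_digest("ACGT") == sequence_digest("acgt")
#' @export
sequence_digest <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (grepl("[[:space:]]", sequence))
    stop("sequence contains whitespace")
  sha512t24u(toupper(sequence))
}

#' Namespace a digest with a refget-style prefix
#'
#' @param digest A digest string.
#' @param prefix Short namespace token without `"."`, e.g. `"SQ"`.
#' @return `paste0(prefix, ".", digest)`.
#' @examples
#' prefixed_identifier(sha512t24u("ACGT"), "SQ")
#' @export
prefixed_identifier <- function(digest, prefix = "SQ") {
  stopifnot(is.character(prefix), length(prefix) == 1L)
  if (!nzchar(prefix) || grepl(".", prefix, fixed = TRUE))
    stop("`prefix` must be a non-empty token without '.'")
  paste0(prefix, ".", digest)
}

#' @rdname prefixed_identifier
#' @export
strip_prefix <- function(digest) {
  sub("^[^.]+\\.", "", digest)
}

is_digest_string <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[A-Za-z0-9_-]{32}$", x)
}
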