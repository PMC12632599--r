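# RFC 8785 (JSON Canonicalization Scheme) serializer.
#
# R value convention (matches jsonlite::fromJSON(..., simplifyVector = FALSE)):
#   - NULL                      -> null
#   - length-1 unclassed atomic -> scalar (string / number / boolean)
#   - atomic vector (length!=1) -> array of scalars
#   - unnamed list              -> array
#   - named list                -> object
# A zero-length list is treated as an object when it carries a names
# attribute and as an array otherwise; wrap length-1 atomics in as.list()
# to force a one-element array.

#' Canonicalize a JSON value (RFC 8785)
#'
#' Serializes an R representation of a JSON value into the unique canonical
#' JSON text defined by RFC 8785 (the JSON Canonicalization Scheme, JCS):
#' no insignificant whitespace, object members sorted by UTF-16 code units
#' of their names, strings minimally escaped, and numbers rendered with the
#' ECMAScript number-to-string algorithm.  All content-derived identifiers
#' in this package are digests of canonical bytes, so two JSON texts that
#' parse to the same value always receive the same digest.
#'
#' @param value An R value following the jsonlite
#'   `fromJSON(simplifyVector = FALSE)` convention: named lists are objects,
#'   unnamed lists are arrays, length-one unclassed atomics are scalars,
#'   and longer atomic vectors are arrays of scalars.
#' @return A raw vector: the UTF-8 bytes of the canonical JSON text.
#' @examples
#' rawToChar(canonicalize_json(list(b = 1L, a = 2L)))  # {"a":2,"b":1}
#' @seealso [sha512t24u()], [seqcol_encode()]
#' @export
canonicalize_json <- function(value) {
  charToRaw(jcs_serialize(value))
}

jcs_serialize <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) || (length(x) == 0L && !is.null(attr(x, "names")))) {
      if (length(x) > 0L && (anyNA(nm) || any(nm == "") || is.null(nm)))
        stop("canonicalization error: object with missing member names")
      if (anyDuplicated(nm))
        stop("canonicalization error: duplicate object member names")
      ord <- jcs_key_order(nm)
      members <- vapply(
        ord,
        function(i) paste0(jcs_string(nm[[i]]), ":", jcs_serialize(x[[i]])),
        character(1)
      )
      return(paste0("{", paste(members, collapse = ","), "}"))
    }
    return(paste0(
      "[", paste(vapply(x, jcs_serialize, character(1)), collapse = ","), "]"
    ))
  }
  if (!is.atomic(x))
    stop("canonicalization error: unsupported type ", class(x)[1])
  if (length(x) != 1L) {
    return(paste0(
      "[",
      paste(vapply(seq_along(x), function(i) jcs_serialize(x[[i]]),
                   character(1)), collapse = ","),
      "]"
    ))
  }
  if (is.character(x)) {
    if (is.na(x)) stop("canonicalization error: NA string")
    return(jcs_string(x))
  }
  if (is.logical(x)) {
    if (is.na(x)) stop("canonicalization error: NA logical (JSON has no NA)")
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) return(jcs_number(as.double(x)))
  stop("canonicalization error: unsupported scalar of type ", typeof(x))
}

# Object member ordering: lexicographic on the UTF-16 code units of the
# (unescaped) member names.  Encoding each code unit as 4 lowercase hex
# digits makes bytewise string order coincide with code-unit order, so a
# C-locale radix sort gives the RFC 8785 ordering.
jcs_key_order <- function(keys) {
  if (length(keys) <= 1L) return(seq_along(keys))
  hex <- vapply(keys, function(k) {
    paste(sprintf("%04x", utf16_units(k)), collapse = "")
  }, character(1))
  order(hex, method = "radix")
}

utf16_units <- function(s) {
  cp <- utf8ToInt(enc2utf8(s))
  if (!length(cp)) return(integer(0))
  if (all(cp <= 0xFFFF)) return(cp)
  unlist(lapply(cp, function(u) {
    if (u <= 0xFFFF) return(u)
    u <- u - 0x10000
    c(0xD800 + u %/% 0x400, 0xDC00 + u %% 0x400)
  }))
}

# JCS string serialization: \", \\, two-character escapes for
# \b \t \n \f \r, \u00xx (lowercase hex) for remaining C0 controls,
# everything else as literal UTF-8.
jcs_string <- function(s) {
  cp <- utf8ToInt(enc2utf8(s))
  if (!length(cp)) return('""')
  out <- vapply(cp, function(u) {
    if (u == 0x22) return('\\"')
    if (u == 0x5C) return("\\\\")
    if (u >= 0x20) return(intToUtf8(u))
    switch(as.character(u),
      "8"  = "\\b",
      "9"  = "\\t",
      "10" = "\\n",
      "12" = "\\f",
      "13" = "\\r",
      sprintf("\\u%04x", u)
    )
  }, character(1))
  paste0('"', paste(out, collapse = ""), '"')
}

# ECMAScript Number::toString(10) (ECMA-262 sec. 6.1.6.1.20), as required
# by RFC 8785: shortest decimal digit string that round-trips, with the
# ES exponent/point placement rules.
jcs_number <- function(x) {
  if (!is.finite(x))
    stop("canonicalization error: non-finite number (NaN/Infinity/NA)")
  if (x == 0) return("0")  # ES String(-0) is "0"
  sign <- if (x < 0) "-" else ""
  m <- abs(x)
  digits <- NULL
  for (p in 1:17) {
    r <- sprintf("%.*e", p - 1L, m)
    if (as.double(r) == m) {
      digits <- r
      break
    }
  }
  mant <- sub("e.*$", "", digits)
  ex <- as.integer(sub("^.*e", "", digits))
  d <- gsub(".", "", mant, fixed = TRUE)
  d <- sub("0+$", "", d)
  if (d == "") d <- "0"
  k <- nchar(d)
  n <- ex + 1L  # value = 0.d1..dk * 10^n
  body <-
    if (k <= n && n <= 21L) {
      paste0(d, strrep("0", n - k))
    } else if (0L < n && n <= 21L) {
      paste0(substr(d, 1L, n), ".", substr(d, n + 1L, k))
    } else if (-6L < n && n <= 0L) {
      paste0("0.", strrep("0", -n), d)
    } else {
      e <- n - 1L
      esign <- if (e >= 0L) "+" else "-"
      mantissa <- if (k == 1L) d else
        paste0(substr(d, 1L, 1L), ".", substr(d, 2L, k))
      paste0(mantissa, "e", esign, abs(e))
    }
  paste0(sign, body)
}
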