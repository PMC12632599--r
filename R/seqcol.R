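# The sequence-collection data model and the five-step encoding algorithm.
#
# A collection is represented canonically as collated (parallel) arrays:
# names, lengths, and sequences (refget sequence identifiers).  Identity is
# computed layer-wise: each inherent attribute is canonicalized (RFC 8785)
# and digested individually (level 1), then the map of inherent attribute
# digests is canonicalized and digested again to give the top-level
# (level 0) digest.  Non-inherent computed attributes (name_length_pairs,
# sorted_name_length_pairs, sorted_sequences) are digested into level 1
# for discovery/filtering but never contribute to level 0.

#' Construct a canonical sequence collection
#'
#' @param names Character vector of sequence names.
#' @param lengths Integer-valued vector of residue counts (>= 0).
#' @param sequences Character vector of sequence identifiers (refget
#'   digests, usually `"SQ."`-prefixed), or `NULL` for a
#'   coordinate-system-only collection.
#' @return An object of class `seqcol`: a named list of collated arrays.
#' @examples
#' seqcol(c("chr1", "chr2"), c(8L, 4L),
#'        prefixed_identifier(c(sequence_digest("ACGTACGT"),
#'                              sequence_digest("TTGG"))))
#' @export
seqcol <- function(names, lengths, sequences = NULL) {
  stopifnot(is.character(names), is.numeric(lengths))
  if (anyNA(names) || anyNA(lengths))
    stop("names and lengths must not contain NA")
  if (any(lengths < 0) || any(lengths != trunc(lengths)))
    stop("lengths must be non-negative integers")
  if (length(names) != length(lengths))
    stop("collated arrays differ in length: names (", length(names),
         ") vs lengths (", length(lengths), ")")
  if (!is.null(sequences)) {
    stopifnot(is.character(sequences))
    if (anyNA(sequences)) stop("sequences must not contain NA")
    if (length(sequences) != length(names))
      stop("collated arrays differ in length: sequences (",
           length(sequences), ") vs names (", length(names), ")")
  }
  if (length(names) == 0L)
    warning("empty sequence collection: identity is the digest of empty arrays")
  x <- list(names = as.character(names), lengths = as.numeric(lengths))
  if (!is.null(sequences)) x$sequences <- as.character(sequences)
  structure(x, class = "seqcol")
}

#' Collate sequence records into a canonical collection
#'
#' Restructures per-sequence records (rows) into the collated-array
#' representation, preserving input order — order is part of identity.
#'
#' @param records A data.frame with columns `name`, `length` and
#'   optionally `sequence_digest` (prefixed sequence identifiers).
#' @return A [seqcol()] object.
#' @export
build_canonical <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("name", "length") %in% names(records)))
  seqs <- if ("sequence_digest" %in% names(records))
    records$sequence_digest else NULL
  seqcol(records$name, records$length, seqs)
}

n_sequences <- function(x) length(x$names)

#' Computed convenience attributes
#'
#' `compute_name_length_pairs()` zips names and lengths into per-sequence
#' `{length, name}` objects, in collection order — a concrete coordinate
#' system.  `compute_sorted_name_length_pairs()` canonicalizes and digests
#' each pair individually, then sorts the digest strings bytewise; the
#' result identifies a coordinate system irrespective of sequence order.
#' `compute_sorted_sequences()` is the bytewise-sorted copy of the
#' sequences array (duplicates preserved), an order-invariant fingerprint
#' of sequence content.
#'
#' @param x A [seqcol()] object.
#' @return `compute_name_length_pairs()`: unnamed list of
#'   `list(length=, name=)` pairs; the other two: character vectors.
#' @export
compute_name_length_pairs <- function(x) {
  stopifnot(inherits(x, "seqcol"))
  lapply(seq_len(n_sequences(x)), function(i) {
    list(length = x$lengths[[i]], name = x$names[[i]])
  })
}

#' @rdname compute_name_length_pairs
#' @export
compute_sorted_name_length_pairs <- function(x) {
  pairs <- compute_name_length_pairs(x)
  d <- vapply(pairs, function(p) sha512t24u(canonicalize_json(p)),
              character(1))
  sort(d, method = "radix")
}

#' @rdname compute_name_length_pairs
#' @export
compute_sorted_sequences <- function(x) {
  stopifnot(inherits(x, "seqcol"))
  if (is.null(x$sequences)) stop("collection has no sequences attribute")
  sort(x$sequences, method = "radix")
}

# Level-2 JSON value of a collection under a schema: named list of arrays
# (arrays as unnamed lists so one-element arrays stay arrays).
seqcol_level2 <- function(x, schema = default_seqcol_schema()) {
  stopifnot(inherits(x, "seqcol"))
  out <- list()
  for (attr in names(schema$attributes)) {
    val <- switch(attr,
      names     = as.list(x$names),
      lengths   = as.list(x$lengths),
      sequences = if (!is.null(x$sequences)) as.list(x$sequences),
      name_length_pairs = compute_name_length_pairs(x),
      sorted_name_length_pairs =
        as.list(compute_sorted_name_length_pairs(x)),
      sorted_sequences =
        if (!is.null(x$sequences)) as.list(compute_sorted_sequences(x)),
      x[[attr]]
    )
    if (!is.null(val)) out[[attr]] <- val
  }
  out
}

#' Encode a sequence collection into its digests
#'
#' Runs the encoding algorithm: (1) collate into canonical representation;
#' (2) canonicalize each inherent attribute value individually (RFC 8785);
#' (3) digest each canonical value with [sha512t24u()] (level 1);
#' (4) canonicalize the map attribute-name to attribute-digest, restricted
#' to inherent attributes; (5) digest that map to obtain the top-level
#' (level 0) identifier.  Non-inherent computed attributes are digested
#' into level 1 as well but are excluded from the level-0 input, so
#' collections differing only in conveniences share an identity.
#'
#' @param x A [seqcol()] object, or a level-2 named list of arrays.
#' @param schema A [seqcol_schema()]; defaults to the base schema.
#' @return An object of class `seqcol_digested` with elements
#'   `digest` (level-0 string), `level1` (named character vector of
#'   attribute digests), `level2` (the full attribute values), and
#'   `warnings` (character vector, e.g. duplicate names).
#' @examples
#' sc <- seqcol("chr1", 4L, prefixed_identifier(sequence_digest("ACGT")))
#' enc <- seqcol_encode(sc)
#' enc$digest
#' @export
seqcol_encode <- function(x, schema = default_seqcol_schema()) {
  if (inherits(x, "seqcol")) {
    level2 <- seqcol_level2(x, schema)
  } else if (is.list(x) && !is.null(names(x))) {
    level2 <- x
  } else {
    stop("`x` must be a seqcol object or a named list (level-2 object)")
  }
  viol <- seqcol_validate(level2, schema)
  hard <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(hard))
    stop("collection violates schema:\n  ",
         paste(sprintf("%s: %s", hard$attribute, hard$message),
               collapse = "\n  "))
  level1 <- vapply(level2, function(v) sha512t24u(canonicalize_json(v)),
                   character(1))
  inh <- intersect(names(level2), inherent_attributes(schema))
  level0_input <- as.list(level1[inh])
  digest <- sha512t24u(canonicalize_json(level0_input))
  structure(
    list(
      digest = digest,
      level1 = level1,
      level2 = level2,
      warnings = viol$message[viol$severity == "warning"]
    ),
    class = "seqcol_digested"
  )
}

#' Validate a level-2 collection object against a schema
#'
#' Violations are returned as data, not raised: a data.frame with columns
#' `attribute`, `severity` (`"error"` or `"warning"`), and `message`.
#' Errors are missing required attributes, mismatched collated-array
#' lengths, negative or non-integral lengths, and wrong element types;
#' duplicate names are legal (identity remains well-defined) but flagged
#' as a warning.
#'
#' @param level2 Named list of attribute values (arrays).
#' @param schema A [seqcol_schema()].
#' @return A data.frame of violations; zero rows iff conforming.
#' @export
seqcol_validate <- function(level2, schema = default_seqcol_schema()) {
  v <- list()
  note <- function(attribute, severity, message) {
    v[[length(v) + 1L]] <<- data.frame(
      attribute = attribute, severity = severity, message = message,
      stringsAsFactors = FALSE
    )
  }
  if (!is.list(level2) || (length(level2) && is.null(names(level2)))) {
    note("(object)", "error", "level-2 representation must be a named object")
    return(do.call(rbind, v))
  }
  for (attr in required_attributes(schema)) {
    if (is.null(level2[[attr]]))
      note(attr, "error", "required attribute missing")
  }
  coll <- intersect(names(level2), collated_attributes(schema))
  if (length(coll)) {
    lens <- vapply(level2[coll], length, integer(1))
    if (length(unique(lens)) > 1L) {
      note(paste(coll, collapse = ","), "error",
           paste0("collated arrays differ in length (",
                  paste(sprintf("%s=%d", coll, lens), collapse = ", "), ")"))
    }
  }
  lengths_val <- level2$lengths
  if (!is.null(lengths_val)) {
    lv <- unlist(lengths_val, use.names = FALSE)
    if (!is.numeric(lv) && length(lv)) {
      note("lengths", "error", "lengths must be numeric")
    } else if (length(lv)) {
      if (any(is.na(lv)) || any(lv != trunc(lv)))
        note("lengths", "error", "lengths must be integral")
      else if (any(lv < 0))
        note("lengths", "error", "lengths must be non-negative")
    }
  }
  nm <- level2$names
  if (!is.null(nm)) {
    nmv <- unlist(nm, use.names = FALSE)
    if (length(nmv) && !is.character(nmv))
      note("names", "error", "names must be strings")
    else if (anyDuplicated(nmv))
      note("names", "warning",
           paste("duplicate sequence names:",
                 paste(unique(nmv[duplicated(nmv)]), collapse = ", ")))
  }
  sq <- level2$sequences
  if (!is.null(sq)) {
    sqv <- unlist(sq, use.names = FALSE)
    if (length(sqv) && !is.character(sqv))
      note("sequences", "error", "sequences must be identifier strings")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(attribute = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Serialize a digested collection at a representation level
#'
#' Level 0 is the bare top-level digest string; level 1 the map of
#' attribute digests; level 2 the full attribute values.
#'
#' @param x A `seqcol_digested` object.
#' @param level 0, 1 or 2.
#' @param json If `TRUE`, return canonical JSON text instead of an R value.
#' @export
seqcol_representation <- function(x, level = 2, json = FALSE) {
  stopifnot(inherits(x, "seqcol_digested"))
  rep <- switch(as.character(level),
    "0" = x$digest,
    "1" = as.list(x$level1),
    "2" = x$level2,
    stop("`level` must be 0, 1 or 2")
  )
  if (json) {
    if (level == 0) jsonlite::toJSON(rep, auto_unbox = TRUE)
    else rawToChar(canonicalize_json(rep))
  } else rep
}

#' @export
print.seqcol <- function(x, ...) {
  cat(sprintf("<seqcol> %d sequence(s)%s\n", n_sequences(x),
              if (is.null(x$sequences)) " (coordinate system only)" else ""))
  n <- min(n_sequences(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %12s  %s\n", x$names[[i]],
                format(x$lengths[[i]], big.mark = ","),
                if (is.null(x$sequences)) "" else x$sequences[[i]]))
  }
  if (n_sequences(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
print.seqcol_digested <- function(x, ...) {
  cat("<seqcol_digested>\n")
  cat("  level 0:", x$digest, "\n")
  for (a in names(x$level1))
    cat(sprintf("  level 1 %-26s %s\n", a, x$level1[[a]]))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
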