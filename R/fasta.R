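# FASTA ingestion.  A streaming core hands records to a callback one at a
# time, so digesting a genome never holds more than one record's residues
# in memory; the convenience reader and the digester are both built on it.

#' Stream FASTA records to a callback
#'
#' Parses a (optionally gzip-compressed) FASTA file record by record.
#' Line endings are normalized (CRLF accepted), blank lines are tolerated,
#' and residue lines are concatenated with whitespace stripped.  The file
#' is read in bounded line chunks; at no point is more than one record's
#' residue string materialized.
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @param callback `function(name, header, residues, index)` invoked once
#'   per record, in file order.
#' @param name_policy `"first-token"` (default; name = first
#'   whitespace-delimited header token, the near-universal aligner
#'   convention) or `"full-header"`.
#' @param strict If `TRUE`, residues outside the IUPAC nucleotide codes
#'   (plus `N` and `-`) are rejected.  Independently of this flag, `*` and
#'   digits are always rejected (they indicate protein or quality data).
#' @param chunk_lines Lines per read; bounds parser memory.
#' @return Invisibly, the number of records streamed.
#' @export
fasta_stream <- function(path, callback,
                         name_policy = c("first-token", "full-header"),
                         strict = FALSE, chunk_lines = 4096L) {
  name_policy <- match.arg(name_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))

  header <- NULL
  parts <- character(0)
  idx <- 0L
  seen_any <- FALSE

  flush_record <- function() {
    residues <- paste(parts, collapse = "")
    check_residues(residues, header, strict)
    idx <<- idx + 1L
    name <- if (name_policy == "first-token")
      sub("[[:space:]].*$", "", header) else header
    if (!nzchar(name)) stop("FASTA format error: empty sequence name")
    callback(name = name, header = header, residues = residues, index = idx)
  }

  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (!length(lines)) break
    lines <- sub("\r$", "", lines)
    for (line in lines) {
      if (!nzchar(line)) next
      if (startsWith(line, ">")) {
        if (!is.null(header)) flush_record()
        header <- sub("^>[[:space:]]*", "", line)
        parts <- character(0)
        seen_any <- TRUE
      } else {
        if (is.null(header))
          stop("FASTA format error: sequence data before first '>' header")
        parts[[length(parts) + 1L]] <- gsub("[[:space:]]", "", line)
      }
    }
  }
  if (!seen_any) stop("FASTA format error: empty file (no records)")
  flush_record()
  invisible(idx)
}

check_residues <- function(residues, header, strict) {
  if (grepl("[*0-9>]", residues))
    stop("FASTA format error in record '", header,
         "': residue line contains '*', '>' or digits")
  if (strict && grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv-]", residues))
    stop("FASTA format error in record '", header,
         "': residues outside IUPAC nucleotide alphabet (strict mode)")
}

#' Read a FASTA file into memory
#'
#' @inheritParams fasta_stream
#' @return A data.frame with columns `name`, `header`, `residues`, in file
#'   order.
#' @export
read_fasta <- function(path, name_policy = c("first-token", "full-header"),
                       strict = FALSE) {
  name_policy <- match.arg(name_policy)
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  fasta_stream(path, function(name, header, residues, index) {
    acc$rows[[index]] <- list(name = name, header = header,
                              residues = residues)
  }, name_policy = name_policy, strict = strict)
  data.frame(
    name = vapply(acc$rows, `[[`, character(1), "name"),
    header = vapply(acc$rows, `[[`, character(1), "header"),
    residues = vapply(acc$rows, `[[`, character(1), "residues"),
    stringsAsFactors = FALSE
  )
}

#' Digest a FASTA file into a sequence collection
#'
#' Streams the file, computing for each record its name (per
#' `name_policy`), its length (count of all residue characters, including
#' `N` and IUPAC ambiguity codes), and its refget sequence digest
#' (uppercased residues), then collates and encodes the collection.
#' Line wrapping and soft-masking therefore never affect the result.
#'
#' @inheritParams fasta_stream
#' @param schema A [seqcol_schema()].
#' @param seq_prefix Namespace prepended to sequence digests (default
#'   `"SQ"`, the refget convention), or `NA` to disable.  Changing this
#'   changes every digest downstream, so it is surfaced here rather than
#'   buried in internals.
#' @return A `seqcol_digested` object (see [seqcol_encode()]); duplicate
#'   names are reported in its `warnings`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "ACGT", "AC"), fa)
#' digest_fasta(fa)$digest
#' @export
digest_fasta <- function(path, schema = default_seqcol_schema(),
                         name_policy = c("first-token", "full-header"),
                         strict = FALSE, seq_prefix = "SQ") {
  name_policy <- match.arg(name_policy)
  acc <- new.env(parent = emptyenv())
  acc$name <- character(0)
  acc$len <- numeric(0)
  acc$dig <- character(0)
  fasta_stream(path, function(name, header, residues, index) {
    acc$name[[index]] <- name
    acc$len[[index]] <- nchar(residues)
    d <- sequence_digest(residues)
    acc$dig[[index]] <-
      if (is.na(seq_prefix)) d else prefixed_identifier(d, seq_prefix)
  }, name_policy = name_policy, strict = strict)
  sc <- seqcol(acc$name, acc$len, acc$dig)
  seqcol_encode(sc, schema)
}
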