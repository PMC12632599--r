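# Independent oracles and small generators shared across tests.
# The digest oracle deliberately uses a different hashing stack
# (digest + base64enc) than the implementation (openssl + jsonlite).

oracle_sha512t24u <- function(data) {
  if (is.character(data)) data <- charToRaw(enc2utf8(data))
  h <- digest::digest(data, algo = "sha512", serialize = FALSE, raw = TRUE)
  chartr("+/", "-_", sub("=+$", "", base64enc::base64encode(h[1:24])))
}

# Brute-force set scores by explicit enumeration over unique elements.
oracle_scores <- function(x, y) {
  ux <- unique(as.character(x))
  uy <- unique(as.character(y))
  inter <- sum(ux %in% uy)
  uni <- length(ux) + length(uy) - inter
  list(
    jaccard = if (uni == 0) NA_real_ else inter / uni,
    opa = if (length(ux) == 0) NA_real_ else inter / length(ux),
    opb = if (length(uy) == 0) NA_real_ else inter / length(uy)
  )
}

# Brute-force set relation by direct membership tests.
oracle_relation <- function(x, y) {
  ux <- unique(as.character(x))
  uy <- unique(as.character(y))
  if (!length(ux) && !length(uy)) return(NA_character_)
  if (setequal(ux, uy)) return("identical-as-sets")
  if (length(ux) && all(ux %in% uy)) return("a-subset-of-b")
  if (length(uy) && all(uy %in% ux)) return("b-subset-of-a")
  if (!any(ux %in% uy)) return("disjoint")
  "partial-overlap"
}

random_json_value <- function(depth = 0L) {
  kind <- sample(c("string", "int", "bool", "null",
                   if (depth < 3L) c("array", "object")), 1L)
  switch(kind,
    string = paste(sample(c(letters, LETTERS, 0:9, " ", "\"", "\\", "/",
                            "é", "€", "\n", "\t"),
                          sample(0:8, 1L), replace = TRUE), collapse = ""),
    int = sample(-1e6:1e6, 1L),
    bool = sample(c(TRUE, FALSE), 1L),
    null = NULL,
    array = lapply(seq_len(sample(0:4, 1L)),
                   function(i) random_json_value(depth + 1L)),
    object = {
      n <- sample(0:4, 1L)
      nms <- make.unique(vapply(seq_len(n), function(i)
        paste(sample(c(letters, LETTERS, "_", "ü"),
                     sample(1:6, 1L), replace = TRUE), collapse = ""),
        character(1)))
      v <- lapply(seq_len(n), function(i) random_json_value(depth + 1L))
      names(v) <- nms
      v
    }
  )
}

# Re-serialize a JSON value with randomized whitespace and member order,
# returning text that parses back to the same value.
messy_json_text <- function(v) {
  ws <- function() paste(rep(" ", sample(0:2, 1L)), collapse = "")
  if (is.null(v)) return(paste0(ws(), "null", ws()))
  if (is.list(v)) {
    nm <- names(v)
    if (!is.null(nm)) {
      ord <- sample(seq_along(v))
      inner <- vapply(ord, function(i) paste0(
        ws(), as.character(jsonlite::toJSON(nm[[i]], auto_unbox = TRUE)),
        ws(), ":", messy_json_text(v[[i]])), character(1))
      return(paste0(ws(), "{", paste(inner, collapse = ","), "}", ws()))
    }
    inner <- vapply(v, messy_json_text, character(1))
    return(paste0(ws(), "[", paste(inner, collapse = ","), "]", ws()))
  }
  paste0(ws(), as.character(jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA)),
         ws())
}

write_tmp_fasta <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

# Encoded collections of the deterministic fixture universe, computed
# once per test run.
universe_collections <- local({
  cache <- NULL
  function(seed = 42L) {
    if (is.null(cache)) {
      u <- build_test_universe(seed)
      dir <- file.path(tempdir(), sprintf("seqcol-universe-%d", seed))
      write_universe(u, dir)
      cols <- resolve_manifest(file.path(dir, "manifest.tsv"))
      cache <<- list(universe = u, dir = dir, collections = cols)
    }
    cache
  }
})
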