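# Pluggable collection stores.  Attribute values are stored once, keyed
# by their level-1 digest, mirroring the layered digest design: two
# collections sharing a lengths array share one stored lengths value.
# Backends: in-memory environments, and a single-file SQLite database
# (requires the DBI + RSQLite packages).

#' Create a collection store
#'
#' @param backend `"memory"` or `"sqlite"`.
#' @param path Database file for the sqlite backend (`":memory:"` works).
#' @param schema The [seqcol_schema()] this store serves.
#' @return An object of class `seqcol_store` supporting [store_add()],
#'   [store_get()], [store_list()], [store_attribute()].
#' @export
seqcol_store <- function(backend = c("memory", "sqlite"),
                         path = ":memory:",
                         schema = default_seqcol_schema()) {
  backend <- match.arg(backend)
  st <- new.env(parent = emptyenv())
  st$schema <- schema
  st$backend <- backend
  if (backend == "memory") {
    st$collections <- new.env(parent = emptyenv())  # digest -> level1 list
    st$attributes <- new.env(parent = emptyenv())   # "attr|digest" -> value
    st$order <- character(0)                        # insertion order
  } else {
    for (pkg in c("DBI", "RSQLite"))
      if (!requireNamespace(pkg, quietly = TRUE))
        stop("the sqlite backend needs the ", pkg, " package")
    st$con <- DBI::dbConnect(RSQLite::SQLite(), path)
    reg.finalizer(st, function(e) {
      if (!is.null(e$con) && DBI::dbIsValid(e$con))
        DBI::dbDisconnect(e$con)
    }, onexit = TRUE)
    DBI::dbExecute(st$con, "
      CREATE TABLE IF NOT EXISTS collections (
        seq INTEGER PRIMARY KEY AUTOINCREMENT,
        digest TEXT UNIQUE NOT NULL,
        level1 TEXT NOT NULL
      )")
    DBI::dbExecute(st$con, "
      CREATE TABLE IF NOT EXISTS attribute_values (
        attribute TEXT NOT NULL,
        digest TEXT NOT NULL,
        value TEXT NOT NULL,
        PRIMARY KEY (attribute, digest)
      )")
  }
  class(st) <- "seqcol_store"
  st
}

#' Store operations
#'
#' `store_add()` registers a digested collection and returns its level-0
#' digest; re-adding an identical collection is a no-op returning the same
#' digest.  `store_get()` retrieves a stored collection at level 0, 1
#' or 2.  `store_list()` pages through stored digests in insertion order,
#' optionally filtered by an attribute's level-1 digest.
#' `store_attribute()` retrieves a single attribute value by its level-1
#' digest.  `store_size()` reports storage accounting (collections and
#' deduplicated attribute values held).
#'
#' @param store A [seqcol_store()].
#' @param x A `seqcol_digested` (or coercible) object.
#' @return `store_add()`: the level-0 digest string.
#' @export
store_add <- function(store, x) {
  d <- as_digested(x, store$schema)
  if (store$backend == "memory") {
    if (!exists(d$digest, envir = store$collections, inherits = FALSE)) {
      assign(d$digest, as.list(d$level1), envir = store$collections)
      store$order <- c(store$order, d$digest)
    }
    for (attr in names(d$level1)) {
      key <- paste0(attr, "|", d$level1[[attr]])
      if (!exists(key, envir = store$attributes, inherits = FALSE))
        assign(key, d$level2[[attr]], envir = store$attributes)
    }
  } else {
    DBI::dbExecute(store$con,
      "INSERT OR IGNORE INTO collections (digest, level1) VALUES (?, ?)",
      params = list(d$digest,
                    rawToChar(canonicalize_json(as.list(d$level1)))))
    for (attr in names(d$level1)) {
      DBI::dbExecute(store$con,
        "INSERT OR IGNORE INTO attribute_values (attribute, digest, value)
         VALUES (?, ?, ?)",
        params = list(attr, d$level1[[attr]],
                      rawToChar(canonicalize_json(d$level2[[attr]]))))
    }
  }
  d$digest
}

store_level1 <- function(store, digest) {
  if (store$backend == "memory") {
    if (!exists(digest, envir = store$collections, inherits = FALSE))
      return(NULL)
    get(digest, envir = store$collections, inherits = FALSE)
  } else {
    r <- DBI::dbGetQuery(store$con,
      "SELECT level1 FROM collections WHERE digest = ?",
      params = list(digest))
    if (!nrow(r)) return(NULL)
    jsonlite::fromJSON(r$level1[[1]], simplifyVector = FALSE)
  }
}

#' @param digest A level-0 digest string.
#' @param level 0, 1 or 2.
#' @rdname store_add
#' @export
store_get <- function(store, digest, level = 2) {
  l1 <- store_level1(store, digest)
  if (is.null(l1)) return(NULL)
  if (level == 0) return(digest)
  if (level == 1) return(l1)
  if (level != 2) stop("`level` must be 0, 1 or 2")
  out <- lapply(names(l1), function(attr)
    store_attribute(store, attr, l1[[attr]]))
  names(out) <- names(l1)
  out
}

#' @param page Zero-based page index.
#' @param page_size Results per page (capped at 1000).
#' @param filter Optional named list `attribute = level1-digest`; only
#'   collections whose attribute digest matches every entry are listed.
#' @rdname store_add
#' @export
store_list <- function(store, page = 0L, page_size = 100L, filter = NULL) {
  if (page < 0L || page_size < 1L || page_size > 1000L)
    stop("bad paging parameters")
  digests <- if (store$backend == "memory") store$order else
    DBI::dbGetQuery(store$con,
      "SELECT digest FROM collections ORDER BY seq")$digest
  if (!is.null(filter) && length(filter)) {
    known <- names(store$schema$attributes)
    bad <- setdiff(names(filter), known)
    if (length(bad))
      stop("unknown filter attribute(s): ", paste(bad, collapse = ", "))
    keep <- vapply(digests, function(d) {
      l1 <- store_level1(store, d)
      all(vapply(names(filter), function(a)
        identical(l1[[a]], filter[[a]]), logical(1)))
    }, logical(1))
    digests <- digests[keep]
  }
  total <- length(digests)
  lo <- page * page_size + 1L
  hi <- min(total, (page + 1L) * page_size)
  items <- if (lo > total) character(0) else digests[lo:hi]
  list(
    results = as.list(items),
    pagination = list(page = page, page_size = page_size, total = total)
  )
}

#' @param attribute Attribute name.
#' @param attr_digest The attribute's level-1 digest.
#' @rdname store_add
#' @export
store_attribute <- function(store, attribute, attr_digest) {
  if (store$backend == "memory") {
    key <- paste0(attribute, "|", attr_digest)
    if (!exists(key, envir = store$attributes, inherits = FALSE))
      return(NULL)
    get(key, envir = store$attributes, inherits = FALSE)
  } else {
    r <- DBI::dbGetQuery(store$con,
      "SELECT value FROM attribute_values WHERE attribute = ? AND digest = ?",
      params = list(attribute, attr_digest))
    if (!nrow(r)) return(NULL)
    jsonlite::fromJSON(r$value[[1]], simplifyVector = FALSE)
  }
}

#' @rdname store_add
#' @export
store_size <- function(store) {
  if (store$backend == "memory") {
    list(
      collections = length(store$order),
      attribute_values = length(ls(store$attributes))
    )
  } else {
    list(
      collections = DBI::dbGetQuery(
        store$con, "SELECT COUNT(*) AS n FROM collections")$n,
      attribute_values = DBI::dbGetQuery(
        store$con, "SELECT COUNT(*) AS n FROM attribute_values")$n
    )
  }
}

#' @export
print.seqcol_store <- function(x, ...) {
  sz <- store_size(x)
  cat(sprintf("<seqcol_store backend=%s> %d collection(s), %d attribute value(s)\n",
              x$backend, sz$collections, sz$attribute_values))
  invisible(x)
}
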