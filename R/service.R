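# Retrieval and comparison API.  All endpoint logic lives in a pure
# request router over a seqcol_store, so the behaviour is testable
# in-process; seqcol_serve() binds the same router to an HTTP port via
# httpuv.  Endpoints:
#   GET /service-info
#   GET /collection/{digest}?level=1|2          (default 2)
#   GET /comparison/{digestA}/{digestB}
#   POST /comparison/{digestA}                  (level-2 JSON body)
#   GET /list/collections?page&page_size&{attr}={attr-digest}
#   GET /attribute/collection/{attribute}/{digest}
# Write access is deliberately not exposed over HTTP: collections are
# bulk-loaded through store_add() / the CLI, matching a retrieval-only
# service.

service_info <- function(store) {
  list(
    id = "org.seqcolr.service",
    name = "seqcolr sequence collections service",
    type = list(group = "org.ga4gh", artifact = "refget-seqcol",
                version = "1.0.0"),
    description =
      "Retrieval and comparison API for content-addressed sequence collections",
    seqcol = list(schema = schema_as_list(store$schema))
  )
}

api_error <- function(status, message) {
  list(status = status,
       body = list(error = message, status = status))
}

#' Handle one API request
#'
#' The router behind [seqcol_serve()]; useful directly for in-process
#' conformance testing.  Paths and semantics follow the standard's
#' retrieval/comparison API.
#'
#' @param store A [seqcol_store()].
#' @param method `"GET"` or `"POST"`.
#' @param path Request path, e.g. `"/collection/<digest>"`.
#' @param query Named list of query parameters (all strings).
#' @param body For `POST /comparison/...`: a level-2 object (named list)
#'   or a JSON string.
#' @return A list with `status` (integer) and `body` (R value; serialize
#'   with canonical JSON for the wire).
#' @export
seqcol_request <- function(store, method, path, query = list(), body = NULL) {
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (method == "GET" && identical(parts, "service-info"))
    return(list(status = 200L, body = service_info(store)))

  if (method == "GET" && length(parts) == 2L && parts[1] == "collection") {
    digest <- parts[2]
    if (!is_digest_string(digest))
      return(api_error(400L, "malformed collection digest"))
    level <- query$level %||% "2"
    if (!level %in% c("0", "1", "2"))
      return(api_error(400L, "unknown level (use 0, 1 or 2)"))
    rep <- store_get(store, digest, level = as.integer(level))
    if (is.null(rep))
      return(api_error(404L, paste0("collection not found: ", digest)))
    return(list(status = 200L, body = rep))
  }

  if (length(parts) >= 2L && parts[1] == "comparison") {
    da <- parts[2]
    if (!is_digest_string(da))
      return(api_error(400L, "malformed collection digest"))
    a2 <- store_get(store, da, level = 2)
    if (is.null(a2))
      return(api_error(404L, paste0("collection not found: ", da)))
    if (method == "GET" && length(parts) == 3L) {
      db <- parts[3]
      if (!is_digest_string(db))
        return(api_error(400L, "malformed collection digest"))
      b2 <- store_get(store, db, level = 2)
      if (is.null(b2))
        return(api_error(404L, paste0("collection not found: ", db)))
      cmp <- seqcol_compare(a2, b2, schema = store$schema)
      return(list(status = 200L, body = comparison_as_list(cmp)))
    }
    if (method == "POST" && length(parts) == 2L) {
      if (is.character(body))
        body <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                         error = function(e) NULL)
      if (!is.list(body) || is.null(names(body)))
        return(api_error(422L, "body must be a level-2 collection object"))
      viol <- seqcol_validate(body, store$schema)
      if (any(viol$severity == "error"))
        return(api_error(422L, paste(viol$message[viol$severity == "error"],
                                     collapse = "; ")))
      cmp <- seqcol_compare(a2, body, schema = store$schema)
      res <- comparison_as_list(cmp)
      res$digests["b"] <- list(NULL)  # ad hoc collection: no stored digest
      return(list(status = 200L, body = res))
    }
  }

  if (method == "GET" && identical(parts, c("list", "collections"))) {
    page <- suppressWarnings(as.integer(query$page %||% "0"))
    page_size <- suppressWarnings(as.integer(query$page_size %||% "100"))
    if (is.na(page) || is.na(page_size) || page < 0L ||
        page_size < 1L || page_size > 1000L)
      return(api_error(400L, "bad paging parameters"))
    filter <- query[setdiff(names(query), c("page", "page_size"))]
    if (length(filter)) {
      bad <- setdiff(names(filter), names(store$schema$attributes))
      if (length(bad))
        return(api_error(400L, paste("unknown filter attribute:",
                                     paste(bad, collapse = ", "))))
    }
    res <- store_list(store, page = page, page_size = page_size,
                      filter = if (length(filter)) filter else NULL)
    return(list(status = 200L, body = res))
  }

  if (method == "GET" && length(parts) == 4L &&
      parts[1] == "attribute" && parts[2] == "collection") {
    attribute <- parts[3]
    adigest <- parts[4]
    if (!attribute %in% names(store$schema$attributes))
      return(api_error(404L, paste0("unknown attribute: ", attribute)))
    val <- store_attribute(store, attribute, adigest)
    if (is.null(val))
      return(api_error(404L, paste0("attribute value not found: ", adigest)))
    return(list(status = 200L, body = val))
  }

  api_error(404L, paste0("no such route: ", method, " ", path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serve the API over HTTP
#'
#' Binds [seqcol_request()] to a port with httpuv.  Responses are
#' serialized as canonical JSON (level-0 lookups return a JSON string).
#' Runs until interrupted unless `blocking = FALSE`, in which case the
#' server handle is returned and must be stopped with
#' `httpuv::stopServer()`.
#'
#' @param store A [seqcol_store()], typically pre-loaded via
#'   [store_add()].
#' @param port TCP port.
#' @param host Interface to bind.
#' @param blocking Run the event loop in this process.
#' @export
seqcol_serve <- function(store, port = 8976L, host = "127.0.0.1",
                         blocking = TRUE) {
  if (!requireNamespace("httpuv", quietly = TRUE))
    stop("seqcol_serve() needs the httpuv package")
  app <- list(
    call = function(req) {
      query <- parse_query_string(req$QUERY_STRING %||% "")
      body <- NULL
      if (identical(req$REQUEST_METHOD, "POST")) {
        body <- tryCatch(rawToChar(req$rook.input$read()),
                         error = function(e) NULL)
      }
      res <- seqcol_request(store, req$REQUEST_METHOD, req$PATH_INFO,
                            query = query, body = body)
      payload <- if (is.character(res$body) && length(res$body) == 1L &&
                     is.null(names(res$body)))
        as.character(jsonlite::toJSON(res$body, auto_unbox = TRUE))
      else
        rawToChar(canonicalize_json(res$body))
      list(
        status = res$status,
        headers = list("Content-Type" = "application/json"),
        body = payload
      )
    }
  )
  srv <- httpuv::startServer(host, port, app)
  if (!blocking) return(srv)
  on.exit(httpuv::stopServer(srv))
  message(sprintf("seqcol service listening on http://%s:%d", host, port))
  httpuv::service(Inf)
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs)
  if (!nzchar(qs)) return(list())
  kv <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(p) utils::URLdecode(p[2] %||% ""))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}
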