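# Attribute schemas: which attributes a collection carries, which are
# required, which are collated (parallel arrays), and which are inherent
# (hashed into the collection identity).

#' Sequence-collection attribute schemas
#'
#' A schema declares the attributes of a sequence collection and their
#' status.  *Inherent* attributes contribute to the top-level digest;
#' non-inherent attributes (typically the computed conveniences
#' `name_length_pairs`, `sorted_name_length_pairs` and `sorted_sequences`)
#' are carried and served but excluded from identity, so servers offering
#' different conveniences still agree on digests.  *Collated* attributes
#' are parallel arrays sharing one index across the collection.
#'
#' `default_seqcol_schema()` returns the recommended base schema:
#' `names`, `lengths` and `sequences` required, collated and inherent;
#' the three computed attributes non-inherent.
#'
#' @param attributes Named list; each element a list with logical fields
#'   `required`, `collated`, `inherent`.
#' @return An object of class `seqcol_schema`.
#' @examples
#' sch <- default_seqcol_schema()
#' inherent_attributes(sch)
#' @export
seqcol_schema <- function(attributes) {
  stopifnot(is.list(attributes), !is.null(names(attributes)))
  attributes <- lapply(attributes, function(a) {
    list(
      required = isTRUE(a$required),
      collated = isTRUE(a$collated),
      inherent = isTRUE(a$inherent)
    )
  })
  if (!any(vapply(attributes, `[[`, logical(1), "inherent")))
    stop("schema must declare at least one inherent attribute")
  structure(list(attributes = attributes), class = "seqcol_schema")
}

#' @rdname seqcol_schema
#' @export
default_seqcol_schema <- function() {
  seqcol_schema(list(
    names     = list(required = TRUE,  collated = TRUE,  inherent = TRUE),
    lengths   = list(required = TRUE,  collated = TRUE,  inherent = TRUE),
    sequences = list(required = TRUE,  collated = TRUE,  inherent = TRUE),
    name_length_pairs =
                list(required = FALSE, collated = TRUE,  inherent = FALSE),
    sorted_name_length_pairs =
                list(required = FALSE, collated = FALSE, inherent = FALSE),
    sorted_sequences =
                list(required = FALSE, collated = FALSE, inherent = FALSE)
  ))
}

#' Coordinate-system schema (no concrete sequences)
#'
#' Schema for collections that carry names and lengths only, identifying a
#' coordinate system without sequence content.
#' @rdname seqcol_schema
#' @export
coordinate_system_schema <- function() {
  seqcol_schema(list(
    names   = list(required = TRUE,  collated = TRUE, inherent = TRUE),
    lengths = list(required = TRUE,  collated = TRUE, inherent = TRUE),
    name_length_pairs =
              list(required = FALSE, collated = TRUE, inherent = FALSE),
    sorted_name_length_pairs =
              list(required = FALSE, collated = FALSE, inherent = FALSE)
  ))
}

#' @rdname seqcol_schema
#' @export
inherent_attributes <- function(schema) {
  stopifnot(inherits(schema, "seqcol_schema"))
  names(Filter(function(a) a$inherent, schema$attributes))
}

#' @rdname seqcol_schema
#' @export
required_attributes <- function(schema) {
  stopifnot(inherits(schema, "seqcol_schema"))
  names(Filter(function(a) a$required, schema$attributes))
}

collated_attributes <- function(schema) {
  names(Filter(function(a) a$collated, schema$attributes))
}

#' Read / write a schema as a JSON Schema document
#'
#' The on-disk form follows JSON Schema conventions: a `properties` map,
#' a `required` array, plus two extension keywords, `inherent` and
#' `collated`, each an array of attribute names.
#'
#' @param path File path of a JSON schema document.
#' @return `read_seqcol_schema()`: a `seqcol_schema`.
#' @export
read_seqcol_schema <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  props <- names(doc$properties)
  if (is.null(props)) stop("schema file has no 'properties'")
  attributes <- lapply(props, function(p) {
    list(
      required = p %in% doc$required,
      collated = p %in% doc$collated,
      inherent = p %in% doc$inherent
    )
  })
  names(attributes) <- props
  seqcol_schema(attributes)
}

#' @param schema A `seqcol_schema`.
#' @rdname read_seqcol_schema
#' @export
write_seqcol_schema <- function(schema, path) {
  stopifnot(inherits(schema, "seqcol_schema"))
  props <- lapply(schema$attributes, function(a) {
    list(type = "array")
  })
  doc <- list(
    description = "sequence collection attribute schema",
    type = "object",
    properties = props,
    required = required_attributes(schema),
    collated = collated_attributes(schema),
    inherent = inherent_attributes(schema)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.seqcol_schema <- function(x, ...) {
  cat("<seqcol_schema>\n")
  for (nm in names(x$attributes)) {
    a <- x$attributes[[nm]]
    flags <- c(
      if (a$required) "required",
      if (a$collated) "collated",
      if (a$inherent) "inherent" else "non-inherent"
    )
    cat(sprintf("  %-26s %s\n", nm, paste(flags, collapse = ", ")))
  }
  invisible(x)
}

# JSON-value form used by /service-info
schema_as_list <- function(schema) {
  list(
    type = "object",
    properties = lapply(schema$attributes, function(a) list(type = "array")),
    required = as.list(required_attributes(schema)),
    collated = as.list(collated_attributes(schema)),
    inherent = as.list(inherent_attributes(schema))
  )
}
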