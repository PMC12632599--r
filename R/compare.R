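# The comparison protocol: attribute partition, shared-element counts and
# order flags, Jaccard / overlap-proportion scores, set-relationship
# classification, and plain-language interpretation.
#
# Element counts use unique elements (set semantics, matching the score
# definitions); a duplicate flag is recorded per attribute and same-order
# is undefined under duplicates.  Scores are carried as integer counts
# (exact rationals) so the opa == 1 subset boundary never depends on
# floating-point ties.

# Comparable string key for each array element (elements may be strings,
# numbers, or objects such as name-length pairs).
element_keys <- function(values) {
  if (is.null(values)) return(character(0))
  if (is.character(values)) return(values)
  if (is.atomic(values)) return(vapply(values, jcs_serialize, character(1)))
  vapply(values, function(v) {
    if (is.character(v) && length(v) == 1L) v else jcs_serialize(v)
  }, character(1))
}

#' Compare two sequence collections
#'
#' Computes the standard comparison result: the partition of attribute
#' names into a-only / b-only / shared, and for every shared collated
#' attribute the number of unique elements in each collection, the number
#' shared, and whether the shared elements appear in the same relative
#' order.  `same_order` is `NA` (undefined) when either filtered array
#' contains duplicates or fewer than two elements are shared.  The result
#' is label-symmetric: `compare(b, a)` equals `compare(a, b)` with the
#' a/b fields exchanged.
#'
#' @param a,b `seqcol_digested` objects (see [seqcol_encode()],
#'   [digest_fasta()]), `seqcol` objects, or level-2 named lists.
#' @param schema Schema used to encode plain inputs.
#' @return An object of class `seqcol_comparison`: a list with elements
#'   `digests`, `attributes`, and `array_elements` mirroring the wire
#'   format of the `/comparison` endpoint.
#' @examples
#' a <- seqcol(c("chr1", "chr2"), c(4, 2),
#'             prefixed_identifier(c(sequence_digest("ACGT"),
#'                                   sequence_digest("TT"))))
#' b <- seqcol(c("1", "2"), c(4, 2),
#'             prefixed_identifier(c(sequence_digest("ACGT"),
#'                                   sequence_digest("TT"))))
#' seqcol_compare(a, b)
#' @export
seqcol_compare <- function(a, b, schema = default_seqcol_schema()) {
  da <- as_digested(a, schema)
  db <- as_digested(b, schema)
  attrs_a <- names(da$level2)
  attrs_b <- names(db$level2)
  shared <- sort(intersect(attrs_a, attrs_b), method = "radix")

  counts_a <- counts_b <- counts_ab <- stats::setNames(
    vector("list", length(shared)), shared)
  same_order <- stats::setNames(vector("list", length(shared)), shared)
  dup_flag <- stats::setNames(logical(length(shared)), shared)

  for (attr in shared) {
    ka <- element_keys(da$level2[[attr]])
    kb <- element_keys(db$level2[[attr]])
    ua <- unique(ka)
    ub <- unique(kb)
    inter <- intersect(ua, ub)
    counts_a[[attr]] <- length(ua)
    counts_b[[attr]] <- length(ub)
    counts_ab[[attr]] <- length(inter)
    dup_flag[[attr]] <- anyDuplicated(ka) > 0L || anyDuplicated(kb) > 0L
    fa <- ka[ka %in% inter]
    fb <- kb[kb %in% inter]
    same_order[[attr]] <-
      if (anyDuplicated(fa) || anyDuplicated(fb) || length(inter) < 2L)
        NA
      else
        identical(fa, fb)
  }

  structure(list(
    digests = list(a = da$digest, b = db$digest),
    attributes = list(
      a_only = sort(setdiff(attrs_a, attrs_b), method = "radix"),
      b_only = sort(setdiff(attrs_b, attrs_a), method = "radix"),
      a_and_b = shared
    ),
    array_elements = list(
      a = counts_a,
      b = counts_b,
      a_and_b = counts_ab,
      a_and_b_same_order = same_order
    ),
    duplicates = as.list(dup_flag)
  ), class = "seqcol_comparison")
}

as_digested <- function(x, schema = default_seqcol_schema()) {
  if (inherits(x, "seqcol_digested")) return(x)
  seqcol_encode(x, schema)
}

#' Similarity scores between two element lists
#'
#' `jaccard_index()` is the intersection over the union of the unique
#' elements; `overlap_proportions()` divides the intersection by the size
#' of either set (`opa` for the first argument, `opb` for the second), so
#' `opa == 1` means A is contained in B.  Both are `NA` (undefined, and
#' excluded from aggregate averages) when the relevant set is empty.
#' `similarity_scores()` computes all three together along with the exact
#' integer counts they derive from.
#'
#' @param x,y Vectors or lists of elements; duplicates are collapsed.
#' @return `similarity_scores()`: a `seqcol_scores` list with `jaccard`,
#'   `opa`, `opb`, and counts `intersection`, `union`, `n_a`, `n_b`.
#' @examples
#' jaccard_index(c("p", "q", "r"), c("q", "r", "s"))  # 0.5
#' overlap_proportions(c("p", "q"), c("p", "q", "r"))
#' @export
similarity_scores <- function(x, y) {
  ux <- unique(element_keys(x))
  uy <- unique(element_keys(y))
  ni <- length(intersect(ux, uy))
  nu <- length(union(ux, uy))
  structure(list(
    jaccard = if (nu == 0L) NA_real_ else ni / nu,
    opa = if (length(ux) == 0L) NA_real_ else ni / length(ux),
    opb = if (length(uy) == 0L) NA_real_ else ni / length(uy),
    intersection = ni, union = nu,
    n_a = length(ux), n_b = length(uy)
  ), class = "seqcol_scores")
}

#' @rdname similarity_scores
#' @export
jaccard_index <- function(x, y) similarity_scores(x, y)$jaccard

#' @rdname similarity_scores
#' @export
overlap_proportions <- function(x, y) {
  s <- similarity_scores(x, y)
  c(opa = s$opa, opb = s$opb)
}

#' Classify the set relationship of A to B
#'
#' Pure function of the similarity scores, following the standard decision
#' table: Jaccard 1 means identical as sets; OPA 1 with OPB below 1 means
#' A is a strict subset of B (and symmetrically); Jaccard 0 means
#' disjoint; anything else is partial overlap.  When exact counts are
#' available (a `seqcol_scores` object) the decision uses integer
#' comparisons, avoiding float ties at the subset boundary.
#'
#' @param scores A `seqcol_scores` object from [similarity_scores()], or a
#'   numeric vector/list with elements `jaccard`, `opa`, `opb`.
#' @return One of `"identical-as-sets"`, `"a-subset-of-b"`,
#'   `"b-subset-of-a"`, `"partial-overlap"`, `"disjoint"`, or `NA` when
#'   the scores are undefined (both sets empty).
#' @export
classify_relationship <- function(scores) {
  if (inherits(scores, "seqcol_scores")) {
    ni <- scores$intersection
    na <- scores$n_a
    nb <- scores$n_b
    if (na == 0L && nb == 0L) return(NA_character_)
    if (ni == na && ni == nb) return("identical-as-sets")
    if (na > 0L && ni == na) return("a-subset-of-b")
    if (nb > 0L && ni == nb) return("b-subset-of-a")
    if (ni == 0L) return("disjoint")
    return("partial-overlap")
  }
  j <- scores[["jaccard"]]
  opa <- scores[["opa"]]
  opb <- scores[["opb"]]
  if (is.na(j)) return(NA_character_)
  if (!is.na(opa) && !is.na(opb) && (j > opa + 1e-12 || j > opb + 1e-12))
    stop("inconsistent scores: jaccard exceeds an overlap proportion")
  if (j == 1) return("identical-as-sets")
  if (!is.na(opa) && opa == 1) return("a-subset-of-b")
  if (!is.na(opb) && opb == 1) return("b-subset-of-a")
  if (j == 0) return("disjoint")
  "partial-overlap"
}

#' Per-attribute scores and verdicts from a comparison
#'
#' @param comparison A `seqcol_comparison` from [seqcol_compare()].
#' @return A data.frame with one row per shared collated attribute:
#'   counts, `jaccard`, `opa`, `opb`, `same_order`, and `relation`.
#' @export
comparison_scores <- function(comparison) {
  stopifnot(inherits(comparison, "seqcol_comparison"))
  ae <- comparison$array_elements
  attrs <- names(ae$a_and_b)
  rows <- lapply(attrs, function(attr) {
    na <- ae$a[[attr]]
    nb <- ae$b[[attr]]
    ni <- ae$a_and_b[[attr]]
    nu <- na + nb - ni
    s <- structure(list(
      jaccard = if (nu == 0L) NA_real_ else ni / nu,
      opa = if (na == 0L) NA_real_ else ni / na,
      opb = if (nb == 0L) NA_real_ else ni / nb,
      intersection = ni, union = nu, n_a = na, n_b = nb
    ), class = "seqcol_scores")
    so <- ae$a_and_b_same_order[[attr]]
    data.frame(
      attribute = attr, n_a = na, n_b = nb, intersection = ni,
      jaccard = s$jaccard, opa = s$opa, opb = s$opb,
      same_order = if (is.null(so)) NA else so,
      relation = classify_relationship(s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Interpret a comparison in plain language
#'
#' Derives one observation per shared collated attribute purely from the
#' counts and order flags, naming the compatibility levels the comparison
#' protocol is designed to surface: full identity, order-relaxed identity
#' (same element sets, different order), name-relaxed identity (matching
#' sequence content under different names), shared or subset coordinate
#' systems (via `name_length_pairs`), subset relationships, and
#' disjointness.
#'
#' @param comparison A `seqcol_comparison` from [seqcol_compare()].
#' @return A data.frame with columns `attribute`, `relation`,
#'   `same_order`, `observation`; plus a `summary` attribute carrying
#'   collection-level observations.
#' @export
interpret_comparison <- function(comparison) {
  sc <- comparison_scores(comparison)
  obs <- character(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    attr <- sc$attribute[i]
    rel <- sc$relation[i]
    so <- sc$same_order[i]
    obs[i] <- if (is.na(rel)) {
      sprintf("Attribute '%s' is empty in both collections.", attr)
    } else switch(rel,
      "identical-as-sets" =
        if (isTRUE(so))
          sprintf("Attribute '%s' is identical in content and order.", attr)
        else if (identical(so, FALSE))
          sprintf(paste0("Attribute '%s' holds the same elements in a ",
                         "different order (order-relaxed identity)."), attr)
        else
          sprintf("Attribute '%s' holds the same element set.", attr),
      "a-subset-of-b" =
        sprintf("Attribute '%s' of A is a strict subset of B's (%d of %d).",
                attr, sc$intersection[i], sc$n_b[i]),
      "b-subset-of-a" =
        sprintf("Attribute '%s' of B is a strict subset of A's (%d of %d).",
                attr, sc$intersection[i], sc$n_a[i]),
      "disjoint" =
        sprintf("Attribute '%s' shares no elements between A and B.", attr),
      "partial-overlap" =
        sprintf("Attribute '%s' overlaps partially: %d shared of %d in A and %d in B.",
                attr, sc$intersection[i], sc$n_a[i], sc$n_b[i])
    )
  }
  summary <- character(0)
  rel_of <- function(a) if (a %in% sc$attribute)
    sc$relation[sc$attribute == a] else NA_character_
  so_of <- function(a) if (a %in% sc$attribute)
    sc$same_order[sc$attribute == a] else NA
  # NA order flags (duplicates, or < 2 shared elements) do not contradict
  # identity; only an explicit FALSE does
  if (all(sc$relation %in% "identical-as-sets") &&
      !any(vapply(sc$same_order, isFALSE, logical(1)))) {
    summary <- c(summary, "The collections are identical.")
  }
  if (identical(rel_of("sequences"), "identical-as-sets") &&
      identical(rel_of("names"), "disjoint")) {
    summary <- c(summary, paste(
      "Sequence content matches under entirely different names",
      "(name-relaxed identity)."))
  }
  if (identical(rel_of("sequences"), "identical-as-sets") &&
      identical(so_of("sequences"), FALSE)) {
    summary <- c(summary,
      "Sequences match as a set but are ordered differently (order-relaxed identity).")
  }
  if (identical(rel_of("name_length_pairs"), "identical-as-sets")) {
    summary <- c(summary, "The collections share a coordinate system.")
  } else if (identical(rel_of("name_length_pairs"), "a-subset-of-b")) {
    summary <- c(summary, "A's coordinate system is a subset of B's.")
  } else if (identical(rel_of("name_length_pairs"), "b-subset-of-a")) {
    summary <- c(summary, "B's coordinate system is a subset of A's.")
  }
  out <- data.frame(
    attribute = sc$attribute, relation = sc$relation,
    same_order = sc$same_order, observation = obs,
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- summary
  out
}

# Wire-format JSON value of a comparison result (stable canonical keys).
comparison_as_list <- function(comparison) {
  ae <- comparison$array_elements
  list(
    digests = list(
      a = if (is.null(comparison$digests$a)) NULL else comparison$digests$a,
      b = if (is.null(comparison$digests$b)) NULL else comparison$digests$b
    ),
    attributes = list(
      a_only = as.list(comparison$attributes$a_only),
      b_only = as.list(comparison$attributes$b_only),
      a_and_b = as.list(comparison$attributes$a_and_b)
    ),
    array_elements = list(
      a = ae$a, b = ae$b, a_and_b = ae$a_and_b,
      a_and_b_same_order = lapply(ae$a_and_b_same_order, function(v)
        if (is.na(v)) NULL else v)
    )
  )
}

#' @export
print.seqcol_comparison <- function(x, ...) {
  cat("<seqcol_comparison>\n")
  cat("  a:", if (is.null(x$digests$a)) "(ad hoc)" else x$digests$a, "\n")
  cat("  b:", if (is.null(x$digests$b)) "(ad hoc)" else x$digests$b, "\n")
  print(comparison_scores(x), row.names = FALSE)
  invisible(x)
}
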