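# Batch compatibility analytics over a manifest of collections: pairwise
# score matrices, duplicate / identical-attribute / subset censuses,
# sequence-presence matrices, provider summaries, 1-vs-many comparison,
# and score histograms.  Everything downstream of ingest is deterministic.

#' Read a collection manifest
#'
#' A manifest maps collection files to analysis labels.  Columns: `label`
#' (unique), `provider`, `genome_class` (e.g. `"hg38"`), `path` (FASTA,
#' possibly gzipped).  Tab- or comma-separated by file extension.
#'
#' @param path Manifest file (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @return A data.frame with the four columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  need <- c("label", "provider", "genome_class", "path")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$label))
    stop("manifest labels must be unique; duplicated: ",
         paste(unique(m$label[duplicated(m$label)]), collapse = ", "))
  m[need]
}

#' Digest every collection in a manifest
#'
#' @param manifest A manifest data.frame (see [read_manifest()]); relative
#'   paths are resolved against `base_dir`.
#' @param schema,seq_prefix Passed to [digest_fasta()].
#' @param base_dir Directory against which relative manifest paths
#'   resolve; defaults to the manifest's own directory when `manifest` is
#'   a file path.
#' @return A named list (by label) of `seqcol_digested` objects.
#' @export
resolve_manifest <- function(manifest, schema = default_seqcol_schema(),
                             seq_prefix = "SQ", base_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$label
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!is.null(base_dir) && !file.exists(p))
      p <- file.path(base_dir, manifest$path[i])
    if (!file.exists(p))
      stop("cannot resolve manifest entry '", manifest$label[i],
           "': file not found: ", manifest$path[i])
    out[[i]] <- digest_fasta(p, schema = schema, seq_prefix = seq_prefix)
  }
  out
}

as_collection_list <- function(collections, schema = default_seqcol_schema()) {
  if (is.data.frame(collections)) collections <- resolve_manifest(collections)
  stopifnot(is.list(collections),
            length(collections) == 0L || !is.null(names(collections)))
  lapply(collections, as_digested, schema = schema)
}

#' Pairwise similarity matrices over a set of collections
#'
#' For each requested attribute, computes Jaccard, OPA and OPB matrices
#' over all unordered pairs of collections.  When two collections share
#' the attribute's level-1 digest, the scores are 1 by construction and
#' element comparison is short-circuited (the layered digests make the
#' check O(1)); the flag `short_circuit = FALSE` disables this for
#' cross-checking.
#'
#' @param collections Named list of `seqcol_digested` objects (or a
#'   manifest data.frame, which is resolved first).
#' @param attributes Attribute names to compare; the defaults are the four
#'   used throughout reference-compatibility analysis.
#' @param short_circuit Use level-1 digest equality to skip element
#'   comparison for identical attribute values.
#' @return A named list (by attribute) of `seqcol_pairwise` objects:
#'   `labels`, and square matrices `jaccard`, `opa`, `opb` where
#'   `opa[i, j]` is the overlap proportion with respect to collection i
#'   (so `opa[i, j] == opb[j, i]`).
#' @export
pairwise_matrices <- function(collections,
                              attributes = c("names", "lengths", "sequences",
                                             "name_length_pairs"),
                              short_circuit = TRUE) {
  cols <- as_collection_list(collections)
  labels <- names(cols)
  n <- length(labels)
  keys <- lapply(cols, function(d)
    lapply(d$level2[attributes], function(v) unique(element_keys(v))))
  out <- list()
  for (attr in attributes) {
    J <- A <- B <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      ki <- keys[[i]][[attr]]
      if (length(ki)) J[i, i] <- A[i, i] <- B[i, i] <- 1
      if (i == n) next
      for (j in seq((i + 1L), n)) {
        di <- cols[[i]]$level1[[attr]]
        dj <- cols[[j]]$level1[[attr]]
        if (short_circuit && !is.null(di) && !is.null(dj) &&
            identical(di, dj)) {
          J[i, j] <- J[j, i] <- 1
          A[i, j] <- A[j, i] <- B[i, j] <- B[j, i] <- 1
          next
        }
        kj <- keys[[j]][[attr]]
        s <- similarity_scores(ki, kj)
        J[i, j] <- J[j, i] <- s$jaccard
        A[i, j] <- s$opa; B[i, j] <- s$opb
        A[j, i] <- s$opb; B[j, i] <- s$opa
      }
    }
    out[[attr]] <- structure(
      list(attribute = attr, labels = labels,
           jaccard = J, opa = A, opb = B),
      class = "seqcol_pairwise"
    )
  }
  out
}

#' Census of duplicate collections
#'
#' Groups collections by their top-level digest.  The duplicate fraction
#' is `(n_total - n_distinct) / n_total` — the share of collections that
#' are redundant copies of another under a different label.  For
#' transparency the alternative reading (members of multi-label groups
#' over total) is reported alongside.
#'
#' @inheritParams pairwise_matrices
#' @return A list: `groups` (label vectors sharing one digest, size > 1),
#'   `n_total`, `n_distinct`, `duplicate_fraction`, and
#'   `member_fraction`.
#' @export
find_duplicates <- function(collections) {
  cols <- as_collection_list(collections)
  digests <- vapply(cols, `[[`, character(1), "digest")
  groups <- if (length(digests)) split(names(digests), digests) else list()
  dup_groups <- Filter(function(g) length(g) > 1L, groups)
  n_total <- length(digests)
  n_distinct <- length(groups)
  list(
    groups = unname(dup_groups),
    n_total = n_total,
    n_distinct = n_distinct,
    duplicate_fraction =
      if (n_total == 0L) NA_real_ else (n_total - n_distinct) / n_total,
    member_fraction =
      if (n_total == 0L) NA_real_ else
        sum(lengths(dup_groups)) / n_total
  )
}

#' Census of identical attribute values
#'
#' Groups collections sharing one attribute's level-1 digest — e.g. all
#' collections with identical lengths arrays, regardless of names or
#' sequence content.
#'
#' @inheritParams pairwise_matrices
#' @param attribute Attribute name, e.g. `"lengths"`.
#' @return As [find_duplicates()], keyed on the attribute digest.
#' @export
find_identical_attribute_sets <- function(collections, attribute) {
  cols <- as_collection_list(collections)
  digests <- vapply(cols, function(d) {
    d1 <- d$level1[[attribute]]
    if (is.null(d1) || is.na(d1)) NA_character_ else d1
  }, character(1))
  digests <- digests[!is.na(digests)]
  groups <- if (length(digests)) split(names(digests), digests) else list()
  dup_groups <- Filter(function(g) length(g) > 1L, groups)
  n_total <- length(digests)
  list(
    attribute = attribute,
    groups = unname(dup_groups),
    n_total = n_total,
    n_distinct = length(groups),
    duplicate_fraction =
      if (n_total == 0L) NA_real_ else (n_total - length(groups)) / n_total
  )
}

#' Census of strict subset relationships
#'
#' Lists ordered pairs (A, B) where the unique elements of `attribute` in
#' A form a strict subset of those in B (overlap proportion of A equal to
#' 1 with Jaccard below 1).  Identical pairs are excluded by strictness.
#'
#' @inheritParams find_identical_attribute_sets
#' @return A data.frame with columns `a`, `b`, `n_a`, `n_b`.
#' @export
find_subsets <- function(collections, attribute) {
  cols <- as_collection_list(collections)
  labels <- names(cols)
  keys <- lapply(cols, function(d)
    unique(element_keys(d$level2[[attribute]])))
  rows <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (i == j) next
      ki <- keys[[i]]; kj <- keys[[j]]
      if (length(ki) && length(ki) < length(kj) && all(ki %in% kj)) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = labels[i], b = labels[j],
          n_a = length(ki), n_b = length(kj),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(),
               n_a = integer(), n_b = integer(), stringsAsFactors = FALSE)
}

#' Sequence presence across a class of references
#'
#' For one genome class (e.g. all hg38-derived references), builds the
#' presence matrix of every sequence identifier appearing in at least one
#' member, and the per-sequence frequency.
#'
#' @param collections Named list of `seqcol_digested` (or manifest
#'   data.frame).
#' @param manifest Manifest data.frame supplying `genome_class` per label.
#' @param genome_class Class to select.
#' @return A list: `presence` (logical matrix, sequences x labels),
#'   `row_frequency` (named integer vector), `genome_class`.
#' @export
sequence_presence <- function(collections, manifest, genome_class) {
  cols <- as_collection_list(collections)
  sel <- manifest$label[manifest$genome_class == genome_class]
  sel <- intersect(sel, names(cols))
  if (!length(sel)) stop("unknown or empty genome class: ", genome_class)
  seqs <- lapply(cols[sel], function(d)
    unique(element_keys(d$level2$sequences)))
  all_ids <- sort(unique(unlist(seqs)), method = "radix")
  presence <- vapply(seqs, function(s) all_ids %in% s,
                     logical(length(all_ids)))
  presence <- matrix(presence, nrow = length(all_ids),
                     dimnames = list(all_ids, sel))
  list(
    presence = presence,
    row_frequency = rowSums(presence),
    genome_class = genome_class
  )
}

#' Per-provider similarity summary
#'
#' For each provider and attribute: the mean Jaccard score and the median
#' pairwise difference (median of 1 - Jaccard) over all unordered pairs
#' involving at least one collection from that provider (or, with
#' `within_only = TRUE`, both members).  Undefined cells are excluded;
#' a provider with no defined pairs reports `NA`.
#'
#' @param matrices Output of [pairwise_matrices()].
#' @param manifest Manifest data.frame mapping labels to providers.
#' @param within_only Restrict to pairs entirely within the provider.
#' @return A data.frame: `provider`, `attribute`, `mean_jaccard`,
#'   `median_difference`, `n_pairs`.
#' @export
provider_summary <- function(matrices, manifest, within_only = FALSE) {
  providers <- sort(unique(manifest$provider))
  rows <- list()
  for (attr in names(matrices)) {
    pm <- matrices[[attr]]
    labels <- pm$labels
    n <- length(labels)
    if (n < 2L) next
    idx <- which(upper.tri(pm$jaccard), arr.ind = TRUE)
    pair_prov_a <- manifest$provider[match(labels[idx[, 1]], manifest$label)]
    pair_prov_b <- manifest$provider[match(labels[idx[, 2]], manifest$label)]
    vals <- pm$jaccard[idx]
    for (prov in providers) {
      involve <- if (within_only)
        pair_prov_a == prov & pair_prov_b == prov
      else
        pair_prov_a == prov | pair_prov_b == prov
      v <- vals[involve & !is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        provider = prov, attribute = attr,
        mean_jaccard = if (length(v)) mean(v) else NA_real_,
        median_difference = if (length(v)) stats::median(1 - v) else NA_real_,
        n_pairs = length(v),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare one collection against many
#'
#' Scores a query collection against every entry, ranking by sequences
#' Jaccard (descending), breaking ties by name-length-pairs Jaccard and
#' then label — the aggregation behind "which hosted reference is my
#' local genome compatible with?".
#'
#' @param query A `seqcol_digested`/`seqcol`/level-2 object.
#' @param collections Named list of collections (or manifest data.frame).
#' @param attributes Attributes to score.
#' @return A data.frame ranked best-first, one row per (label, attribute):
#'   `rank`, `label`, `attribute`, `jaccard`, `opa`, `opb`, `relation`.
#' @export
compare_one_vs_many <- function(query, collections,
                                attributes = c("names", "lengths",
                                               "sequences",
                                               "name_length_pairs")) {
  q <- as_digested(query)
  cols <- as_collection_list(collections)
  qkeys <- lapply(q$level2[attributes], function(v) unique(element_keys(v)))
  per_label <- lapply(names(cols), function(lbl) {
    d <- cols[[lbl]]
    rows <- lapply(attributes, function(attr) {
      s <- similarity_scores(qkeys[[attr]],
                             element_keys(d$level2[[attr]]))
      data.frame(
        label = lbl, attribute = attr,
        jaccard = s$jaccard, opa = s$opa, opb = s$opb,
        relation = classify_relationship(s),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, per_label)
  key <- function(lbl, attr) {
    v <- res$jaccard[res$label == lbl & res$attribute == attr]
    if (!length(v) || is.na(v)) -1 else v
  }
  labels <- names(cols)
  seqj <- vapply(labels, key, numeric(1), attr = "sequences")
  nlpj <- vapply(labels, key, numeric(1), attr = "name_length_pairs")
  ord <- order(-seqj, -nlpj, labels, method = "radix")
  ranked <- labels[ord]
  res$rank <- match(res$label, ranked)
  res <- res[order(res$rank, match(res$attribute, attributes)), ]
  rownames(res) <- NULL
  res[c("rank", "label", "attribute", "jaccard", "opa", "opb", "relation")]
}

#' Histogram of pairwise scores
#'
#' Bins the off-diagonal upper triangle of a score matrix into 20 fixed
#' bins over `[0, 1]`; undefined cells are dropped.  Used for the density
#' maps summarizing how similar a set of references is overall.
#'
#' @param matrix_or_pm A numeric matrix or a `seqcol_pairwise` object
#'   (its Jaccard matrix is used).
#' @return A data.frame: `bin_lo`, `bin_hi`, `count`; total count equals
#'   the number of defined unordered pairs.
#' @export
density_summary <- function(matrix_or_pm) {
  m <- if (inherits(matrix_or_pm, "seqcol_pairwise"))
    matrix_or_pm$jaccard else matrix_or_pm
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  vals <- m[upper.tri(m)]
  vals <- vals[!is.na(vals)]
  breaks <- seq(0, 1, length.out = 21L)
  # right-closed bins except the first, so 0 lands in bin 1 and 1 in bin 20
  bins <- findInterval(vals, breaks, rightmost.closed = TRUE,
                       left.open = TRUE)
  bins[vals == 0] <- 1L
  counts <- tabulate(bins, nbins = 20L)
  data.frame(
    bin_lo = breaks[-21L],
    bin_hi = breaks[-1L],
    count = counts
  )
}

#' Write analysis outputs as deterministic tables
#'
#' Emits every matrix in wide CSV and long TSV form plus the censuses,
#' with sorted, documented column order, so all numbers exist as plain
#' tables before any plotting.
#'
#' @param matrices Output of [pairwise_matrices()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pairwise_tables <- function(matrices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (attr in names(matrices)) {
    pm <- matrices[[attr]]
    for (score in c("jaccard", "opa", "opb")) {
      p <- file.path(dir, sprintf("%s_%s.csv", attr, score))
      utils::write.csv(pm[[score]], p, row.names = TRUE)
      paths <- c(paths, p)
    }
    idx <- which(upper.tri(pm$jaccard), arr.ind = TRUE)
    long <- data.frame(
      a = pm$labels[idx[, 1]], b = pm$labels[idx[, 2]],
      jaccard = pm$jaccard[idx], opa = pm$opa[idx], opb = pm$opb[idx]
    )
    long <- long[order(long$a, long$b, method = "radix"), ]
    p <- file.path(dir, sprintf("%s_pairs.tsv", attr))
    utils::write.table(long, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
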