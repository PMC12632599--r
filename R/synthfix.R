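# Deterministic synthetic-genome fixtures with planted, machine-readable
# ground truth.  The generator emulates the ways real reference providers
# vary a genome: renaming sequences, reordering them, dropping scaffolds
# (no-alt / patch subsetting), soft- and hard-masking, point mutations,
# and decoy additions.  Every derived collection carries a truth record
# stating the expected comparison outcome per attribute, so the whole
# comparison/analysis surface can be verified against construction.
#
# The PRNG is fixed (Mersenne-Twister / Inversion / Rejection) and all
# randomness flows from explicit seeds, so a universe is byte-identical
# across platforms and runs.

with_fixed_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  force(code)
}

#' Generate a random synthetic genome as FASTA text
#'
#' Sequences are named `chr1..chrN` with independently drawn residues
#' from `alphabet` (default ACGT with 1% N, a crude stand-in for assembly
#' gaps).  Deterministic in `seed`.
#'
#' @param n_seqs Number of sequences (>= 1).
#' @param length_range `c(min, max)` residue counts, min >= 1.
#' @param alphabet Residue characters to draw from.
#' @param n_fraction Fraction of positions replaced by `N`.
#' @param seed Integer seed.
#' @param wrap Line width for FASTA output.
#' @param name_prefix Sequence-name prefix (names are `<prefix>1..N`).
#' @return A character scalar: the FASTA file content.
#' @export
generate_genome <- function(n_seqs = 5L, length_range = c(200L, 400L),
                            alphabet = c("A", "C", "G", "T"),
                            n_fraction = 0.01, seed = 1L, wrap = 60L,
                            name_prefix = "chr") {
  stopifnot(n_seqs >= 1L, length(length_range) == 2L)
  if (length_range[1] < 1L || length_range[2] < length_range[1])
    stop("invalid length range")
  with_fixed_rng(seed, {
    recs <- vapply(seq_len(n_seqs), function(i) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      res <- sample(alphabet, len, replace = TRUE)
      if (n_fraction > 0) {
        nn <- rbinom(1L, len, n_fraction)
        if (nn > 0) res[sample.int(len, nn)] <- "N"
      }
      paste0(">", name_prefix, i, "\n",
             wrap_fasta(paste(res, collapse = ""), wrap))
    }, character(1))
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}

wrap_fasta <- function(s, wrap = 60L) {
  n <- nchar(s)
  if (n == 0L) return("")
  starts <- seq(1L, n, by = wrap)
  paste(substring(s, starts, pmin(starts + wrap - 1L, n)), collapse = "\n")
}

parse_fasta_text <- function(fasta) {
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  writeLines(fasta, tmp, sep = "")
  read_fasta(tmp)
}

render_fasta <- function(df, wrap = 60L) {
  recs <- vapply(seq_len(nrow(df)), function(i) {
    paste0(">", df$header[i], "\n", wrap_fasta(df$residues[i], wrap))
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

rename_sequence <- function(name, style) {
  num <- sub("^chr", "", name)
  switch(style,
    ucsc = paste0("chr", num),
    ensembl = num,
    accession = sprintf("SYN%08d.1", suppressWarnings(as.integer(num))),
    stop("unknown rename style: ", style)
  )
}

#' Derive a variant genome with a declared relationship
#'
#' Applies exactly one provider-style transformation to a base genome and
#' returns both the variant FASTA and a truth record stating the expected
#' per-attribute comparison outcome of (base vs variant).
#'
#' Operations: `rename` (new naming style; content untouched), `reorder`
#' (permute records), `subset` (keep the given record indices, order
#' preserved — emulates no-alt derivatives and patch ancestry),
#' `soft_mask` (lowercase a run per record; digest-neutral), `hard_mask`
#' (replace a run per record with `N`; changes every touched sequence
#' digest, lengths unchanged), `point_mutate` (k substitutions within one
#' record; exactly one sequence digest changes), `append_decoys` (add m
#' new records drawn from a disjoint seed stream).
#'
#' @param base FASTA text (e.g. from [generate_genome()]).
#' @param op One of `"rename"`, `"reorder"`, `"subset"`, `"soft_mask"`,
#'   `"hard_mask"`, `"point_mutate"`, `"append_decoys"`.
#' @param style Rename style: `"ucsc"`, `"ensembl"`, `"accession"`.
#' @param keep Indices of records to keep (for `subset`).
#' @param fraction Fraction of each record to mask.
#' @param k Number of point substitutions.
#' @param record Record index to mutate.
#' @param m Number of decoy records to append.
#' @param seed Seed for the stochastic operations.
#' @return A list with `fasta` (character) and `truth` (list: `op`,
#'   parameters, and `expected`, a named list attribute ->
#'   relation-of-base-to-variant in the vocabulary of
#'   [classify_relationship()], plus `expected$level0_equal`).
#' @export
derive_variant <- function(base,
                           op = c("rename", "reorder", "subset", "soft_mask",
                                  "hard_mask", "point_mutate",
                                  "append_decoys"),
                           style = "ensembl", keep = NULL, fraction = 0.1,
                           k = 2L, record = 1L, m = 2L, seed = 1L) {
  op <- match.arg(op)
  df <- parse_fasta_text(base)
  n <- nrow(df)
  identical_all <- list(names = "identical-as-sets",
                        lengths = "identical-as-sets",
                        sequences = "identical-as-sets",
                        name_length_pairs = "identical-as-sets")
  truth <- list(op = op, expected = identical_all)
  truth$expected$level0_equal <- FALSE

  if (op == "rename") {
    new_names <- vapply(df$name, rename_sequence, character(1), style = style)
    collide <- any(new_names == df$name)
    df$header <- new_names
    df$name <- new_names
    truth$style <- style
    truth$expected$names <- if (collide) "partial-overlap" else "disjoint"
    truth$expected$name_length_pairs <- truth$expected$names
  } else if (op == "reorder") {
    if (n < 2L) stop("reorder needs >= 2 records")
    perm <- with_fixed_rng(seed, {
      repeat {
        p <- sample.int(n)
        if (!identical(p, seq_len(n))) break
      }
      p
    })
    df <- df[perm, , drop = FALSE]
    truth$permutation <- perm
    truth$expected$same_order <- FALSE
    truth$expected$sorted_nlp_equal <- TRUE
  } else if (op == "subset") {
    if (is.null(keep) || !length(keep)) stop("subset of zero indices")
    if (any(keep < 1L | keep > n)) stop("subset indices out of range")
    if (length(keep) >= n) stop("subset must drop at least one record")
    df <- df[sort(unique(keep)), , drop = FALSE]
    truth$keep <- sort(unique(keep))
    truth$expected <- list(names = "b-subset-of-a",
                           lengths = "b-subset-of-a",
                           sequences = "b-subset-of-a",
                           name_length_pairs = "b-subset-of-a",
                           level0_equal = FALSE)
  } else if (op %in% c("soft_mask", "hard_mask")) {
    df$residues <- with_fixed_rng(seed, vapply(df$residues, function(res) {
      len <- nchar(res)
      span <- max(1L, as.integer(round(fraction * len)))
      start <- sample.int(len - span + 1L, 1L)
      seg <- substr(res, start, start + span - 1L)
      if (op == "hard_mask" && seg == strrep("N", span)) {
        # run already hard-masked: slide to a start that changes content
        starts <- seq_len(len - span + 1L)
        ok <- starts[vapply(starts, function(s)
          substr(res, s, s + span - 1L) != strrep("N", span), logical(1))]
        if (!length(ok))
          stop("hard_mask cannot change an all-N record")
        start <- ok[1L]
        seg <- substr(res, start, start + span - 1L)
      }
      repl <- if (op == "soft_mask") tolower(seg) else
        strrep("N", nchar(seg))
      paste0(substr(res, 1L, start - 1L), repl,
             substr(res, start + span, len))
    }, character(1), USE.NAMES = FALSE))
    truth$fraction <- fraction
    if (op == "soft_mask") {
      truth$expected$level0_equal <- TRUE
    } else {
      # every record gets >= 1 N, so every sequence digest changes
      truth$expected$sequences <- "disjoint"
    }
  } else if (op == "point_mutate") {
    if (record < 1L || record > n) stop("record index out of range")
    res <- df$residues[record]
    len <- nchar(res)
    if (k > len) stop("k exceeds residue count of record ", record)
    df$residues[record] <- with_fixed_rng(seed, {
      pos <- sample.int(len, k)
      chars <- strsplit(res, "")[[1]]
      for (p in pos) {
        alt <- setdiff(c("A", "C", "G", "T"), toupper(chars[p]))
        chars[p] <- sample(alt, 1L)
      }
      paste(chars, collapse = "")
    })
    truth$k <- k
    truth$record <- record
    truth$expected$sequences <-
      if (n == 1L) "disjoint" else "partial-overlap"
    truth$expected$n_changed_sequence_digests <- 1L
  } else if (op == "append_decoys") {
    # decoys come from a seed stream disjoint from the base generator
    # (offset by a large constant) so collisions with base sequences are
    # ruled out; asserted below.
    decoys <- parse_fasta_text(
      generate_genome(n_seqs = m, length_range = c(80L, 120L),
                      seed = seed + 1000003L)
    )
    decoys$name <- paste0("decoy", seq_len(m))
    decoys$header <- decoys$name
    if (any(decoys$residues %in% df$residues))
      stop("decoy collision with base sequences (seed stream overlap)")
    df <- rbind(df, decoys)
    truth$m <- m
    truth$expected <- list(names = "a-subset-of-b",
                           lengths = "partial-overlap-or-subset",
                           sequences = "a-subset-of-b",
                           name_length_pairs = "a-subset-of-b",
                           level0_equal = FALSE)
    truth$expected$lengths <- NULL  # decoy lengths may collide with base
  }
  list(fasta = render_fasta(df), truth = truth)
}

#' Build the standard fixture universe
#'
#' Generates a deterministic set of 12 synthetic collections covering
#' every relation class the analysis layer must recover: a duplicate
#' group (verbatim copy and a soft-masked copy, which shares the digest
#' by design), a renamed pair, a reordered pair, a strict subset chain of
#' length 3 (patch emulation), a hard-masked pair, a 2-point-mutated
#' pair, a decoy-augmented superset, and a disjoint second genome with
#' its own duplicate.  Labels are assigned to pseudo-providers, with the
#' disjoint genome's provider planted as the similarity outlier.
#'
#' @param seed Integer master seed; every byte of the universe derives
#'   from it.
#' @return A `seqcol_universe`: list with `collections` (named list of
#'   FASTA strings), `manifest` (data.frame: label, provider,
#'   genome_class, path placeholder), `truth` (planted relations,
#'   including `duplicate_groups` and `duplicate_fraction`), and `seed`.
#' @export
build_test_universe <- function(seed = 42L) {
  base <- generate_genome(n_seqs = 5L, length_range = c(200L, 400L),
                          seed = seed)
  # disjoint from base in names (prefix) and lengths (range), so the
  # planted disjoint relation holds for all four analysis attributes
  other <- generate_genome(n_seqs = 4L, length_range = c(500L, 700L),
                           seed = seed + 1L, name_prefix = "ctg")

  v_rename  <- derive_variant(base, "rename", style = "ensembl")
  v_reorder <- derive_variant(base, "reorder", seed = seed + 2L)
  v_noalt   <- derive_variant(base, "subset", keep = 1:3)
  v_noalt2  <- derive_variant(base, "subset", keep = 1:2)
  v_soft    <- derive_variant(base, "soft_mask", fraction = 0.1,
                              seed = seed + 3L)
  v_hard    <- derive_variant(base, "hard_mask", fraction = 0.1,
                              seed = seed + 3L)
  v_mut     <- derive_variant(base, "point_mutate", k = 2L, record = 1L,
                              seed = seed + 4L)
  v_decoy   <- derive_variant(base, "append_decoys", m = 2L,
                              seed = seed + 5L)

  collections <- list(
    base            = base,
    base_copy       = base,
    base_softmask   = v_soft$fasta,
    base_renamed    = v_rename$fasta,
    base_reordered  = v_reorder$fasta,
    base_noalt      = v_noalt$fasta,
    base_noalt_min  = v_noalt2$fasta,
    base_hardmask   = v_hard$fasta,
    base_mut2       = v_mut$fasta,
    base_decoy      = v_decoy$fasta,
    otherA          = other,
    otherA_copy     = other
  )
  manifest <- data.frame(
    label = names(collections),
    provider = c("alpha", "beta", "alpha", "beta", "alpha", "gamma",
                 "gamma", "alpha", "delta", "delta", "outlier", "outlier"),
    genome_class = c(rep("synA", 10L), rep("synB", 2L)),
    path = paste0(names(collections), ".fa"),
    stringsAsFactors = FALSE
  )
  truth <- list(
    seed = seed,
    duplicate_groups = list(
      c("base", "base_copy", "base_softmask"),
      c("otherA", "otherA_copy")
    ),
    # (n_total - n_distinct) / n_total: 12 labels, 9 distinct digests
    duplicate_fraction = 3 / 12,
    rename_pairs = list(list(a = "base", b = "base_renamed",
                             truth = v_rename$truth)),
    reorder_pairs = list(list(a = "base", b = "base_reordered",
                              truth = v_reorder$truth)),
    subset_chain = c("base_noalt_min", "base_noalt", "base"),
    mask_pairs = list(
      list(a = "base", b = "base_softmask", truth = v_soft$truth),
      list(a = "base", b = "base_hardmask", truth = v_hard$truth)
    ),
    mutation_pairs = list(list(a = "base", b = "base_mut2",
                               truth = v_mut$truth)),
    decoy_pairs = list(list(a = "base", b = "base_decoy",
                            truth = v_decoy$truth)),
    outlier_provider = "outlier",
    disjoint_pairs = list(list(a = "base", b = "otherA"))
  )
  structure(list(collections = collections, manifest = manifest,
                 truth = truth, seed = seed),
            class = "seqcol_universe")
}

#' Write a fixture universe to disk
#'
#' Writes each collection as `<label>.fa`, plus `manifest.tsv` and
#' `truth.json`.
#'
#' @param universe A [build_test_universe()] result.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "seqcol_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lbl in names(universe$collections)) {
    con <- file(file.path(dir, paste0(lbl, ".fa")), "wb")
    writeChar(universe$collections[[lbl]], con, eos = NULL)
    close(con)
  }
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(universe$manifest, mpath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(universe$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mpath)
}

#' @export
print.seqcol_universe <- function(x, ...) {
  cat(sprintf("<seqcol_universe> %d collections (seed %d)\n",
              length(x$collections), x$seed))
  print(x$manifest[c("label", "provider", "genome_class")],
        row.names = FALSE)
  invisible(x)
}
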