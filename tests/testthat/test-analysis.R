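# Batch analytics over the fixture universe and small constructed sets.

test_that("manifests are read and resolved with validation", {
  fix <- universe_collections()
  m <- read_manifest(file.path(fix$dir, "manifest.tsv"))
  expect_equal(nrow(m), 12L)
  expect_equal(names(m), c("label", "provider", "genome_class", "path"))
  bad <- m
  bad$label[2] <- bad$label[1]
  f <- tempfile(fileext = ".tsv")
  utils::write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(f), "unique")
  ghost <- m
  ghost$path[1] <- "no-such-file.fa"
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(ghost, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(resolve_manifest(f2), ghost$label[1])
})

test_that("pairwise matrices have the documented shape and symmetries", {
  fix <- universe_collections()
  cols <- fix$collections
  n <- length(cols)
  ms <- pairwise_matrices(cols)
  expect_equal(names(ms), c("names", "lengths", "sequences",
                            "name_length_pairs"))
  for (pm in ms) {
    expect_equal(dim(pm$jaccard), c(n, n))
    expect_true(all(diag(pm$jaccard) == 1))
    expect_equal(pm$jaccard, t(pm$jaccard))
    expect_equal(pm$opa, t(pm$opb))          # opa[i,j] == opb[j,i]
    off <- pm$jaccard[upper.tri(pm$jaccard)]
    expect_true(all(off >= 0 & off <= 1, na.rm = TRUE))
  }
  # duplicated labels of one collection: full similarity off-diagonal
  two <- cols[c("base", "base_copy")]
  pm <- pairwise_matrices(two)$sequences
  expect_true(all(pm$jaccard == 1))
})

test_that("the digest short-circuit changes nothing", {
  fix <- universe_collections()
  cols <- fix$collections
  fast <- pairwise_matrices(cols)
  slow <- pairwise_matrices(cols, short_circuit = FALSE)
  for (attr in names(fast)) {
    expect_identical(fast[[attr]]$jaccard, slow[[attr]]$jaccard)
    expect_identical(fast[[attr]]$opa, slow[[attr]]$opa)
    expect_identical(fast[[attr]]$opb, slow[[attr]]$opb)
  }
})

test_that("duplicate census recovers the planted groups and fraction", {
  fix <- universe_collections()
  dup <- find_duplicates(fix$collections)
  truth <- fix$universe$truth
  got <- lapply(dup$groups, sort)
  want <- lapply(truth$duplicate_groups, sort)
  expect_setequal(got, want)
  expect_equal(dup$duplicate_fraction, truth$duplicate_fraction)
  expect_equal(dup$n_total - dup$n_distinct, 3L)
  # all-distinct set: fraction 0
  distinct <- fix$collections[c("base", "base_renamed", "otherA")]
  expect_equal(find_duplicates(distinct)$duplicate_fraction, 0)
  # stated formula on a constructed case: 10 labels, 3 sharing a digest
  ten <- fix$collections[rep("base_renamed", 3)]
  names(ten) <- paste0("r", 1:3)
  ten <- c(ten, fix$collections[c("base", "base_reordered", "base_noalt",
                                  "base_noalt_min", "base_hardmask",
                                  "base_mut2", "otherA")])
  expect_equal(find_duplicates(ten)$duplicate_fraction, (10 - 8) / 10)
})

test_that("identical-attribute censuses group by level-1 digest", {
  fix <- universe_collections()
  cols <- fix$collections
  by_seq <- find_identical_attribute_sets(cols, "sequences")
  grp <- Filter(function(g) "base" %in% g, by_seq$groups)[[1]]
  # renamed + reordered-as-set? reorder changes order hence digest;
  # the rename keeps the sequences array identical
  expect_true(all(c("base", "base_renamed") %in% grp))
  by_names <- find_identical_attribute_sets(cols, "names")
  grp_n <- Filter(function(g) "base" %in% g, by_names$groups)[[1]]
  expect_false("base_renamed" %in% grp_n)
  expect_true("base_hardmask" %in% grp_n)
  # hard-masked pair: apart for sequences, together for lengths
  by_len <- find_identical_attribute_sets(cols, "lengths")
  grp_l <- Filter(function(g) "base" %in% g, by_len$groups)[[1]]
  expect_true("base_hardmask" %in% grp_l)
  expect_false("base_hardmask" %in% grp)
  expect_equal(length(find_identical_attribute_sets(list(), "names")$groups),
               0L)
})

test_that("subset census lists exactly the strict-subset pairs", {
  fix <- universe_collections()
  cols <- fix$collections[c("base", "base_noalt", "base_noalt_min",
                            "base_renamed", "otherA")]
  for (attr in c("names", "lengths", "sequences", "name_length_pairs")) {
    subs <- find_subsets(cols, attr)
    key <- paste(subs$a, subs$b)
    expect_true(all(c("base_noalt base", "base_noalt_min base",
                      "base_noalt_min base_noalt") %in% key),
                label = attr)
    # strictness: identical pairs and disjoint pairs never listed
    expect_false(any(subs$a == "otherA" | subs$b == "otherA"))
  }
  # renamed shares sequences identically (not strictly) -> not listed
  subs <- find_subsets(cols, "sequences")
  expect_false(any(subs$a == "base_renamed" & subs$b == "base"))
  # no-alt emulation: the subset is detected against every superset
  expect_true(all(c("base_noalt") %in% subs$a))
})

test_that("sequence presence counts per class match brute force", {
  fix <- universe_collections()
  cols <- fix$collections
  m <- fix$universe$manifest
  pres <- sequence_presence(cols, m, "synA")
  # brute-force union of unique sequence sets
  sets <- lapply(cols[m$label[m$genome_class == "synA"]],
                 function(d) unique(unlist(d$level2$sequences)))
  expect_equal(nrow(pres$presence), length(unique(unlist(sets))))
  expect_equal(unname(pres$row_frequency), unname(rowSums(pres$presence)))
  # decoy sequences appear in exactly one collection
  decoy_only <- setdiff(unlist(cols[["base_decoy"]]$level2$sequences),
                        unlist(cols[["base"]]$level2$sequences))
  expect_true(all(pres$row_frequency[decoy_only] == 1))
  # two identical collections: every shared sequence counted twice
  pres2 <- sequence_presence(cols[c("otherA", "otherA_copy")],
                             m, "synB")
  expect_true(all(pres2$row_frequency == 2))
  expect_error(sequence_presence(cols, m, "hg99"), "unknown or empty")
})

test_that("provider summaries average the right pairs", {
  fix <- universe_collections()
  ms <- pairwise_matrices(fix$collections)
  ps <- provider_summary(ms, fix$universe$manifest)
  expect_true(all(ps$mean_jaccard >= 0 & ps$mean_jaccard <= 1, na.rm = TRUE))
  # the planted outlier provider has the lowest sequence similarity
  seqs <- ps[ps$attribute == "sequences", ]
  expect_equal(seqs$provider[which.min(seqs$mean_jaccard)], "outlier")
  # single provider of identical genomes: mean 1, median difference 0
  m2 <- data.frame(label = c("otherA", "otherA_copy"),
                   provider = "solo", genome_class = "synB",
                   path = NA, stringsAsFactors = FALSE)
  ms2 <- pairwise_matrices(fix$collections[m2$label])
  ps2 <- provider_summary(ms2, m2)
  expect_true(all(ps2$mean_jaccard == 1))
  expect_true(all(ps2$median_difference == 0))
})

test_that("one-vs-many ranks the matching entry first", {
  fix <- universe_collections()
  cols <- fix$collections
  res <- compare_one_vs_many(cols[["base"]], cols)
  top <- res[res$rank == 1, ]
  # the query itself (or its digest-identical duplicates) ranks first
  expect_true(top$label[1] %in% c("base", "base_copy", "base_softmask"))
  expect_true(all(top$jaccard == 1))
  # a planted subset of an entry is classified b-subset-of-a from the
  # query side (query base contains base_noalt)
  noalt <- res[res$label == "base_noalt" & res$attribute == "sequences", ]
  expect_equal(noalt$relation, "b-subset-of-a")
  # disjoint entries score zero
  expect_equal(res$jaccard[res$label == "otherA"], rep(0, 4))
  # query that is a subset of an entry: verdict a-subset-of-b
  res2 <- compare_one_vs_many(cols[["base_noalt"]], cols["base_decoy"])
  expect_equal(res2$relation[res2$attribute == "sequences"], "a-subset-of-b")
})

test_that("density summaries bin the defined upper triangle", {
  fix <- universe_collections()
  ms <- pairwise_matrices(fix$collections)
  h <- density_summary(ms$sequences)
  expect_equal(nrow(h), 20L)
  n <- length(fix$collections)
  expect_equal(sum(h$count), n * (n - 1) / 2)
  # all-identical set: all mass in the top bin
  h2 <- density_summary(pairwise_matrices(
    fix$collections[c("base", "base_copy", "base_softmask")])$sequences)
  expect_equal(h2$count[20], 3L)
  expect_equal(sum(h2$count), 3L)
  # two disjoint clusters of identical genomes: mass only at 0 and 1
  h3 <- density_summary(pairwise_matrices(
    fix$collections[c("base", "base_copy", "otherA", "otherA_copy")]
  )$sequences)
  expect_equal(h3$count[1], 4L)   # cross-cluster pairs at 0
  expect_equal(h3$count[20], 2L)  # within-cluster pairs at 1
  expect_equal(sum(h3$count), 6L)
})

test_that("analysis tables are written deterministically", {
  fix <- universe_collections()
  ms <- pairwise_matrices(fix$collections[1:4])
  d1 <- file.path(tempdir(), "tab1")
  d2 <- file.path(tempdir(), "tab2")
  write_pairwise_tables(ms, d1)
  write_pairwise_tables(ms, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "sequences_jaccard.csv")))
  expect_true(file.exists(file.path(d1, "sequences_pairs.tsv")))
})
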