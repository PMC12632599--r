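# Comparison protocol: counts, order flags, scores, classification,
# interpretation.

make_pair <- function(names_a, seqs_a, names_b, seqs_b) {
  list(
    a = seqcol(names_a, nchar(seqs_a),
               prefixed_identifier(vapply(seqs_a, sequence_digest,
                                          character(1)))),
    b = seqcol(names_b, nchar(seqs_b),
               prefixed_identifier(vapply(seqs_b, sequence_digest,
                                          character(1))))
  )
}

test_that("self-comparison reports full overlap in order", {
  # distinct lengths keep every collated array duplicate-free, so
  # same_order is defined for all attributes
  p <- make_pair(c("chr1", "chr2"), c("ACGT", "TTG"),
                 c("chr1", "chr2"), c("ACGT", "TTG"))
  cmp <- seqcol_compare(p$a, p$b)
  expect_equal(cmp$attributes$a_only, character(0))
  expect_equal(cmp$attributes$b_only, character(0))
  for (attr in c("names", "lengths", "sequences")) {
    expect_equal(cmp$array_elements$a_and_b[[attr]],
                 cmp$array_elements$a[[attr]])
    expect_true(isTRUE(cmp$array_elements$a_and_b_same_order[[attr]]))
  }
  expect_equal(cmp$digests$a, cmp$digests$b)
})

test_that("renamed collections share sequences but not names", {
  p <- make_pair(c("chr1", "chr2"), c("ACGT", "TTGG"),
                 c("1", "2"), c("ACGT", "TTGG"))
  cmp <- seqcol_compare(p$a, p$b)
  ae <- cmp$array_elements
  expect_equal(ae$a_and_b$names, 0L)
  expect_equal(ae$a_and_b$sequences, 2L)
  expect_true(isTRUE(ae$a_and_b_same_order$sequences))
  # shared-order undefined for an empty shared set
  expect_true(is.na(ae$a_and_b_same_order$names))
})

test_that("shared elements out of order are detected", {
  p <- make_pair(c("c1", "c2", "c3"), c("AAAA", "CCCC", "GGGG"),
                 c("c3", "c2", "c4"), c("GGGG", "CCCC", "TTTT"))
  cmp <- seqcol_compare(p$a, p$b)
  # shared sequences: GGGG, CCCC; A-order (CCCC,GGGG), B-order (GGGG,CCCC)
  expect_equal(cmp$array_elements$a_and_b$sequences, 2L)
  expect_false(isTRUE(cmp$array_elements$a_and_b_same_order$sequences))
  expect_identical(cmp$array_elements$a_and_b_same_order$sequences, FALSE)
})

test_that("same_order is undefined under duplicates or < 2 shared", {
  a <- seqcol(c("x", "y"), c(2, 2), c("SQ.k", "SQ.k"))  # duplicate digests
  b <- seqcol(c("x", "y"), c(2, 2), c("SQ.k", "SQ.m"))
  cmp <- expect_warning(seqcol_compare(a, b), NA)
  expect_true(is.na(cmp$array_elements$a_and_b_same_order$sequences))
  expect_true(cmp$duplicates$sequences)
  # exactly one shared element: undefined as well
  p <- make_pair(c("c1", "c2"), c("AAAA", "CCCC"),
                 c("c1", "c9"), c("AAAA", "TTTT"))
  cmp <- seqcol_compare(p$a, p$b)
  expect_true(is.na(cmp$array_elements$a_and_b_same_order$sequences))
})

test_that("comparison is label-symmetric", {
  set.seed(41)
  for (i in 1:25) {
    pool <- c("AAT", "CCG", "GGA", "TTC", "ACA", "GTG")
    sa <- sample(pool, sample(2:5, 1L))
    sb <- sample(pool, sample(2:5, 1L))
    p <- make_pair(paste0("a", seq_along(sa)), sa,
                   paste0("a", seq_along(sb)), sb)
    ab <- seqcol_compare(p$a, p$b)
    ba <- seqcol_compare(p$b, p$a)
    expect_equal(ab$digests$a, ba$digests$b)
    expect_equal(ab$attributes$a_only, ba$attributes$b_only)
    expect_equal(ab$array_elements$a, ba$array_elements$b)
    expect_equal(ab$array_elements$a_and_b, ba$array_elements$a_and_b)
    expect_equal(ab$array_elements$a_and_b_same_order,
                 ba$array_elements$a_and_b_same_order)
  }
})

test_that("scores match hand-enumerated examples", {
  expect_equal(jaccard_index(c("p", "q", "r"), c("q", "r", "s")), 0.5)
  expect_equal(jaccard_index(c("p"), c("p")), 1.0)
  expect_equal(jaccard_index(c("p"), c("q")), 0.0)
  expect_true(is.na(jaccard_index(character(0), character(0))))
  op <- overlap_proportions(c("p", "q", "r"), c("q", "r", "s"))
  expect_equal(unname(op), c(2 / 3, 2 / 3))
  # subset: opa 1, opb < 1; swapping exchanges the values
  op <- overlap_proportions(c("p", "q"), c("p", "q", "r"))
  expect_equal(unname(op), c(1, 2 / 3))
  op2 <- overlap_proportions(c("p", "q", "r"), c("p", "q"))
  expect_equal(unname(op2), rev(unname(op)))
})

test_that("scores match the brute-force oracle on random pairs", {
  set.seed(42)
  pool <- paste0("e", 1:8)
  for (i in 1:400) {
    x <- sample(pool, sample(0:6, 1L), replace = TRUE)
    y <- sample(pool, sample(0:6, 1L), replace = TRUE)
    s <- similarity_scores(x, y)
    o <- oracle_scores(x, y)
    expect_equal(s$jaccard, o$jaccard)
    expect_equal(s$opa, o$opa)
    expect_equal(s$opb, o$opb)
    # score invariants
    if (!is.na(s$jaccard)) {
      expect_true(is.na(s$opa) || s$jaccard <= s$opa)
      expect_true(is.na(s$opb) || s$jaccard <= s$opb)
      if (s$jaccard == 1) expect_true(s$opa == 1 && s$opb == 1)
    }
  }
})

test_that("classification reproduces the decision table exhaustively", {
  # all pairs of subsets of a 5-element universe: every set relation
  # (identical / subset / superset / partial / disjoint) is constructed
  # and the classification must match the brute-force relation
  universe <- paste0("u", 1:5)
  subsets <- lapply(0:(2^5 - 1), function(mask)
    universe[bitwAnd(mask, 2^(0:4)) > 0])
  n_checked <- 0L
  for (x in subsets) {
    for (y in subsets) {
      s <- similarity_scores(x, y)
      expect_identical(classify_relationship(s), oracle_relation(x, y))
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 1024L)
  # spot checks on explicit score shapes
  expect_equal(classify_relationship(c(jaccard = 1, opa = 1, opb = 1)),
               "identical-as-sets")
  expect_equal(classify_relationship(c(jaccard = 0.5, opa = 1, opb = 0.5)),
               "a-subset-of-b")
  expect_equal(classify_relationship(c(jaccard = 0, opa = 0, opb = 0)),
               "disjoint")
  expect_error(classify_relationship(c(jaccard = 0.9, opa = 0.5, opb = 0.5)),
               "inconsistent")
})

test_that("interpretation names the standard compatibility levels", {
  # identical collections
  p <- make_pair(c("chr1", "chr2"), c("ACGT", "TTGG"),
                 c("chr1", "chr2"), c("ACGT", "TTGG"))
  obs <- interpret_comparison(seqcol_compare(p$a, p$b))
  expect_true("The collections are identical." %in% attr(obs, "summary"))
  # rename scenario
  p <- make_pair(c("chr1", "chr2"), c("ACGT", "TTGG"),
                 c("1", "2"), c("ACGT", "TTGG"))
  obs <- interpret_comparison(seqcol_compare(p$a, p$b))
  expect_true(any(grepl("name-relaxed", attr(obs, "summary"))))
  # order-relaxed identity
  p <- make_pair(c("chr1", "chr2", "chr3"), c("ACGT", "TTGG", "CCAA"),
                 c("chr3", "chr1", "chr2"), c("CCAA", "ACGT", "TTGG"))
  obs <- interpret_comparison(seqcol_compare(p$a, p$b))
  expect_true(any(grepl("order-relaxed", attr(obs, "summary"))))
  # subset coordinate system
  p <- make_pair(c("chr1", "chr2"), c("ACGT", "TTGG"),
                 c("chr1", "chr2", "chrM"), c("ACGT", "TTGG", "AATT"))
  obs <- interpret_comparison(seqcol_compare(p$a, p$b))
  expect_true(any(grepl("coordinate system is a subset",
                        attr(obs, "summary"))))
  expect_equal(obs$relation[obs$attribute == "sequences"], "a-subset-of-b")
})

test_that("level-1 digest equality coincides with full same-order overlap", {
  fix <- universe_collections()
  cols <- fix$collections
  pairs <- utils::combn(names(cols), 2, simplify = FALSE)
  for (p in pairs) {
    a <- cols[[p[1]]]
    b <- cols[[p[2]]]
    cmp <- seqcol_compare(a, b)
    for (attr in c("names", "lengths", "sequences")) {
      digest_eq <- identical(a$level1[[attr]], b$level1[[attr]])
      ae <- cmp$array_elements
      full_overlap <-
        ae$a_and_b[[attr]] == ae$a[[attr]] &&
        ae$a_and_b[[attr]] == ae$b[[attr]] &&
        !identical(ae$a_and_b_same_order[[attr]], FALSE)
      # equal digests imply equal arrays (hence full overlap, same order);
      # unequal digests with full same-order overlap can only arise from
      # duplicated elements collapsing in the set view
      if (digest_eq) expect_true(full_overlap)
      else if (full_overlap)
        expect_true(cmp$duplicates[[attr]] ||
                      is.na(ae$a_and_b_same_order[[attr]]))
    }
  }
})
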