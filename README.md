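# seqcolr

Content-derived identifiers and compatibility analysis for sequence
collections (reference genomes, transcriptomes, and any other set of
named sequences), implementing the GA4GH refget Sequence Collections
("seqcol") standard in R.

## The problem

Reference genomes circulate under ambiguous human-readable names —
"hg38" from UCSC, Ensembl, NCBI, or a pipeline's private copy are not
the same file, and the differences (renamed chromosomes, dropped
scaffolds, masking, decoys, patches) silently break the integration and
reproduction of downstream analyses.  `seqcolr` addresses this for
anyone who builds or consumes reference-based pipelines:

* **Identification.** Every collection gets a deterministic, globally
  unique identifier computed from its content, with no registry or
  central authority: anyone digesting the same sequences gets the same
  identifier.
* **Retrieval.** An HTTP API serves collections by digest at three
  representation levels.
* **Comparison.** When identifiers differ, a comparison protocol
  quantifies *how* two references relate — shared coordinate systems,
  order-relaxed or name-relaxed identity, subset relationships — instead
  of stopping at "not the same".
* **Survey analytics.** Batch operations reproduce reference-jungle
  studies: pairwise Jaccard/overlap matrices, duplicate and subset
  censuses, per-provider summaries, and sequence-presence matrices.

## The model

A collection is represented as *collated arrays* sharing one index:

```
names     = [ "chr1",  "chr2",  ... ]
lengths   = [ 248956422, 242193529, ... ]
sequences = [ "SQ.aKF498dAxcJAqme6QYQ7EZ07-fiw8Kw2", ... ]
```

where each `sequences` entry is the refget digest of one sequence's
uppercased residues.  Identity is computed in layers with a single
primitive, `sha512t24u(x)` = base64url(SHA-512(x)[1..24]):

1. canonicalize each *inherent* attribute's JSON value (RFC 8785);
2. digest each canonical value → the **level 1** attribute digests;
3. canonicalize the map {attribute → digest} restricted to inherent
   attributes; digest it → the **level 0** (top-level) identifier.

Attributes declared *non-inherent* by the schema — the computed
conveniences `name_length_pairs` (a concrete coordinate system),
`sorted_name_length_pairs` (an order-invariant coordinate-system
identifier) and `sorted_sequences` — are served and digested but never
contribute to level 0.

Comparisons are scored per attribute on unique elements: Jaccard
J = |A∩B|/|A∪B| and the overlap proportions OPA = |A∩B|/|A|,
OPB = |A∩B|/|B|, from which the set relationship is classified
(J = 1 identical; OPA = 1 ∧ OPB < 1: A ⊂ B; symmetrically B ⊂ A;
J = 0 disjoint; otherwise partial overlap).

## Worked example

```r
library(seqcolr)

fa <- tempfile(fileext = ".fa")
writeLines(c(">chr1 demo assembly", "ACGTACGTTGACCGTT", "GGA",
             ">chr2", "TTGGCCAA"), fa)
enc <- digest_fasta(fa)
enc
#> <seqcol_digested>
#>   level 0: wfPeFWSIln3VF2KmipUdQDzdKkRwnnpK
#>   level 1 names                      XEsH8IMZ09CBX17iXEWRagH50VGfARLo
#>   level 1 lengths                    zaH-miacggTOxMfaAp_oKEo--474reAw
#>   level 1 sequences                  BY4hb43yXTFmSn_qzvgZmApg5J93RVAu
#>   level 1 name_length_pairs          KPvTzQdEWM6T_vTN3q32sbM78LSTO4tT
#>   level 1 sorted_name_length_pairs   oYLg62jtodlVtqYsrKKljykesTPLb-Ix
#>   level 1 sorted_sequences           BY4hb43yXTFmSn_qzvgZmApg5J93RVAu
```

The level-0 line is the collection's identifier; the level-1 lines
identify each attribute on its own (two references sharing the
`lengths` digest have byte-identical length arrays, whatever their
names).  Comparing against a copy that renames `chr1`/`chr2` to
`1`/`2`:

```r
fb <- tempfile(fileext = ".fa")
writeLines(c(">1", "ACGTACGTTGACCGTTGGA", ">2", "TTGGCCAA"), fb)
cmp <- seqcol_compare(enc, digest_fasta(fb))
cmp
#> <seqcol_comparison>
#>   a: wfPeFWSIln3VF2KmipUdQDzdKkRwnnpK
#>   b: MKRldFUaTRLUziTyCh65vzKyENP4BY0m
#>                 attribute n_a n_b intersection jaccard opa opb same_order          relation
#>                   lengths   2   2            2       1   1   1       TRUE identical-as-sets
#>         name_length_pairs   2   2            0       0   0   0         NA          disjoint
#>                     names   2   2            0       0   0   0         NA          disjoint
#>                 sequences   2   2            2       1   1   1       TRUE identical-as-sets
#>  sorted_name_length_pairs   2   2            0       0   0   0         NA          disjoint
#>          sorted_sequences   2   2            2       1   1   1       TRUE identical-as-sets

cat(attr(interpret_comparison(cmp), "summary"), sep = "\n")
#> Sequence content matches under entirely different names (name-relaxed identity).
```

The digests differ (names are inherent), but the comparison shows the
two references carry identical sequence content in identical order —
results aligned against either are integrable after renaming.

Batch analytics run off a manifest (`label / provider / genome_class /
path`); `build_test_universe()` generates a fully synthetic 12-genome
universe with planted duplicates, renames, reorders, subset chains,
masking, mutations and decoys for experimentation:

```r
u <- build_test_universe(42)
dir <- tempfile(); write_universe(u, dir)
cols <- resolve_manifest(file.path(dir, "manifest.tsv"))
find_duplicates(cols)$duplicate_fraction
#> [1] 0.25
```

A command-line interface wrapping the same functions is installed at
`inst/cli/seqcol` (`digest`, `compare`, `analyze`, `fixtures`,
`serve`), and `seqcol_serve()` exposes the retrieval/comparison API
over HTTP.

## Scope notes

The package computes refget *sequence* digests but does not serve raw
sequences (the separate refget Sequences service); it does not download
provider genomes (point a manifest at local FASTA files); and the
comparison protocol is deliberately identity-based — a single
nucleotide change yields an unrelated sequence digest, so
near-identity is out of scope.  See `vignettes/seqcol-methods.Rmd` for
the full methods discussion.
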