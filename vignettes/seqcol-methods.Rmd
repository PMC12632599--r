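---
title: "Methods: content-derived identifiers and compatibility analysis for sequence collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: content-derived identifiers and compatibility analysis for sequence collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcolr)
```

# The model

A *sequence collection* is an ordered set of named sequences — a
reference genome, a transcriptome, a decoy set.  `seqcolr` represents
it canonically as collated arrays sharing one index: `names` (sequence
identifiers), `lengths` (residue counts), and `sequences` (refget
digests of the residues).  Order is part of identity: the same
chromosomes in a different order form a different collection, because
coordinate-sorted outputs (BAM headers, genome browsers) depend on
order.  Order-*invariant* questions are answered by the computed
attributes instead (below).

Identity is computed in layers from two primitives:

* `canonicalize_json(v)` — the RFC 8785 canonical serialization of a
  JSON value (sorted members, no whitespace, fixed number/string
  rendering), so identity never depends on serialization accidents;
* `sha512t24u(b)` — SHA-512 truncated to its first 24 bytes,
  base64url-encoded without padding: a fixed 32-character identifier
  with ~2^96 collision resistance, the digest used across the refget
  family.  There is deliberately no algorithm agility: one algorithm,
  one truncation length, so digests are comparable across
  implementations forever.

The encoding algorithm digests each *inherent* attribute's canonical
value individually (level 1), then digests the canonical map
`{attribute: level-1 digest}` restricted to inherent attributes
(level 0, the collection identifier).  The layering means attribute
digests are useful on their own — two collections sharing a `lengths`
digest have byte-identical length arrays — and encoding cost scales
with the number of sequences, not their total length, once sequence
digests are known.

## Inherent and non-inherent attributes

The schema (`default_seqcol_schema()`) declares `names`, `lengths`,
`sequences` as required, collated and inherent.  Three computed
attributes are non-inherent — served and digested into level 1, but
excluded from level 0, so servers offering different conveniences still
agree on identifiers:

* `name_length_pairs` — per-sequence `{length, name}` objects in
  collection order: a concrete coordinate system.  Annotations made on
  two references are positionally transferable when these match, even
  if the underlying sequence content differs.
* `sorted_name_length_pairs` — each pair canonicalized and digested
  individually, then the digest strings sorted bytewise.  This
  identifies a coordinate system *irrespective of sequence order*; it
  stores the sorted digest array (not the pair objects), so its level-1
  digest is order-invariant by construction.
* `sorted_sequences` — the bytewise-sorted `sequences` array
  (duplicates preserved, a multiset fingerprint of content).

Custom schemas are loadable from a JSON-Schema-style file with
`inherent`/`collated` extension keyword arrays
(`read_seqcol_schema()`); a coordinate-system-only schema (no concrete
sequences) ships as `coordinate_system_schema()`.  Adding an inherent
attribute changes every digest, which is the point: the schema is part
of the identity contract, and `/service-info` advertises it so clients
can detect mismatched configurations.

# Numerical and encoding choices

* **Numbers.** RFC 8785 prescribes ECMAScript number-to-string
  rendering; the implementation computes the shortest round-tripping
  decimal and applies the ECMAScript exponent/point placement rules.
  Integral doubles therefore serialize without a decimal point (`4`,
  never `4.0`).  Sequence lengths must be integral — `seqcol_validate()`
  rejects fractional lengths rather than coercing.  NaN/Infinity are
  serialization errors, as JSON has no such values.
* **Member sorting.** RFC 8785 sorts object members by UTF-16 code
  units of the member names.  Keys are mapped to fixed-width hex code
  unit strings and radix-sorted, so supplementary-plane characters sort
  by their surrogate pairs and the order never depends on the session
  locale.
* **Strings.** Serialized as UTF-8 with the scheme's minimal escaping.
  No Unicode normalization (NFC or otherwise) is applied to sequence
  names: bytes as given are identity.  Two names that render identically
  but differ in normalization form are different names; this matches
  the digest-everything-as-bytes philosophy and avoids a dependency on
  normalization tables.
* **Sequence normalization.** Residues are uppercased before digesting,
  consistent with the refget Sequences convention, so soft-masking
  (lowercase) never affects identity while hard-masking (`N`
  substitution) always does.  No normalization beyond case is applied:
  IUPAC ambiguity codes and other residue bytes are digested as-is,
  since inventing further canonicalization would silently merge
  sequences other implementations keep distinct.
* **Sorting of digest arrays** is bytewise (C locale, radix), never
  locale collation — the sorted attributes must be bit-identical across
  machines.
* **Empty collections** are permitted (their identity is the digest of
  empty arrays) but flagged with a warning — they are nearly always an
  ingestion bug.  **Duplicate names** within a collection keep identity
  well-defined, so they are a warning-level validation finding, not an
  error.

# FASTA ingestion

`digest_fasta()` streams records one at a time (never holding more than
one record's residues), tolerates gzip, CRLF and blank lines, and
counts *all* residue characters (including `N` and ambiguity codes) as
length.  Two policies are explicit parameters rather than buried
defaults, because both change digests:

* `name_policy` — the sequence name is the first whitespace-delimited
  header token by default (the near-universal aligner convention);
  `"full-header"` is available.  The full header is retained as
  non-identity metadata.
* `seq_prefix` — `sequences` entries carry the `SQ.` namespace by
  default, the refget identifier form; `NA` disables it.

Residue validation is lax by default (references legitimately contain
IUPAC codes), with a strict IUPAC-only mode; `*` and digits are
rejected even in lax mode, as they indicate protein or quality data.

# Comparison protocol

`seqcol_compare()` reports, per shared attribute, unique-element counts
for A, B and A∩B, plus whether shared elements appear in the same
relative order.  Choices worth stating:

* **Set semantics.**  Counts collapse duplicates, matching the Jaccard
  and overlap-proportion definitions; a per-attribute duplicate flag is
  recorded.  `same_order` filters both arrays to the shared set and
  tests sequence equality; it is *undefined* (`NA`) when either
  filtered array contains duplicates or fewer than two elements are
  shared, because "same order" has no unambiguous meaning there.
* **Exact arithmetic.**  Scores are derived from integer counts, and
  `classify_relationship()` decides subset/identity on counts
  (`|A∩B| == |A|`), not on floating-point equality to 1.0 — the subset
  boundary can never be lost to rounding.  Jaccard of two empty sets is
  undefined (`NA`), not 0 or 1, and excluded from aggregate averages.
* **Classification.**  J = 1 → identical as sets; OPA = 1, OPB < 1 →
  A ⊂ B (strict); symmetrically B ⊂ A; J = 0 → disjoint; otherwise
  partial overlap.  The decision table is verified exhaustively in the
  test suite against brute-force set relations over all subset pairs of
  a 5-element universe.
* **Interpretation.** `interpret_comparison()` derives plain-language
  observations purely from counts and order flags — full identity,
  order-relaxed identity, name-relaxed identity (same content,
  disjoint names), shared or subset coordinate systems, disjointness.

# Batch analytics

`pairwise_matrices()` scores all unordered pairs per attribute, with a
short-circuit: equal level-1 digests imply scores of 1 without element
comparison.  The tests verify the short-circuited and exhaustive paths
agree exactly.  Downstream censuses make three definitional choices the
source material leaves open; each is a documented decision:

* **Duplicate fraction** = (n_total − n_distinct_level0) / n_total: the
  share of collections that are redundant copies of another.  The
  alternative reading (members of multi-label groups / total) is
  computed alongside as `member_fraction` for transparency.
* **Provider aggregation** counts a pair toward a provider if *either*
  member belongs to it (the grouping an outlier analysis wants);
  `within_only = TRUE` gives the within-provider alternative.
* **Median difference** per provider is the median of (1 − Jaccard)
  over that provider's pairs.

`find_subsets()` lists strict subsets (OPA = 1 with Jaccard < 1 on
unique elements); `sequence_presence()` builds the per-class presence
matrix and row frequencies; `density_summary()` bins the defined
off-diagonal upper triangle into 20 fixed bins on [0, 1].  All tabular
outputs are deterministic, sorted CSV/TSV; nothing downstream of ingest
is stochastic.

# Retrieval API

The endpoint logic is a pure router over a store
(`seqcol_request()`), bound to HTTP by `seqcol_serve()` (httpuv); the
conformance tests exercise both the router and a live socket.  Stores
deduplicate attribute values by level-1 digest — two collections
sharing a `lengths` array store one value — mirroring the layered
digest design; backends are in-memory and single-file SQLite.  Write
access is not exposed over HTTP (bulk loading happens through
`store_add()`/the CLI), since the standard describes a retrieval
service.  Level-0 responses are the bare digest string; pagination is
capped at 1000 per page; unknown levels, malformed digests and bad
paging are 400s, unknown digests 404s, invalid POSTed collections 422s.

# The synthetic fixture universe

`build_test_universe(seed)` generates 12 collections emulating how real
providers vary a reference: a verbatim duplicate, a soft-masked copy
(digest-identical by design — this is the uppercase-normalization
contract made into a fixture), a renamed copy (UCSC→Ensembl style), a
reordered copy, a strict subset chain of length 3 (no-alt/patch
ancestry emulation), a hard-masked copy, a 2-point-mutated copy
(exactly one sequence digest moves), a decoy-augmented superset, and a
disjoint second genome with its own duplicate.  Labels carry
pseudo-providers with the disjoint genome's provider planted as the
similarity outlier.

Default scales — 5 sequences of 200–400 bp (the second genome 4 of
500–700 bp, disjoint in names and lengths by construction), ACGT with
1% `N`, 10% masking fraction, k = 2 mutations — are chosen so every
relation class is present and unambiguous at a size where the whole
universe builds in well under a second; the 2-point mutation mirrors
the observation that trivially small edits produce entirely different
sequence digests.  Randomness uses a pinned generator
(Mersenne-Twister/Inversion/Rejection) under explicit seeds, so a
universe is byte-identical across platforms, and decoys draw from a
seed stream offset far from the base stream, with a collision assertion
at generation time.

What the generator does *not* emulate: biologically realistic
composition (GC content, repeats), real assembly patch semantics beyond
append-only subsetting, and real provider naming chaos beyond three
styles.  A green fixture suite therefore establishes that the
*machinery* — digesting, comparison, censuses, serving — is correct
against planted ground truth; it says nothing empirical about real
provider genomes.  Running the analysis layer on real references is
supported via manifests of locally downloaded FASTA files but is
deliberately outside the test suite (no network, no redistribution).

# Known limitations

* Comparison is identity-based per element: a single nucleotide change
  yields an unrelated sequence digest, so near-identity and edit
  distance are invisible by design.
* The wire format follows the standard's prose; byte-level
  interoperability with other servers should be validated against the
  formal specification's conformance fixtures before federating, which
  requires network resources outside this package's tests.
* Raw sequence retrieval (the refget Sequences service) is out of
  scope: the package computes sequence digests but serves only
  collection-level data.
* Canonical JSON number rendering covers IEEE doubles; integers beyond
  2^53 are not representable and are rejected rather than silently
  rounded.
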