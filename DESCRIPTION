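Package: seqcolr
Title: Content-Derived Identifiers and Compatibility Analysis for
    Sequence Collections
Version: 0.9.0
Authors@R:
    person("seqcolr", "developers", email = "seqcolr@example.org",
           role = c("aut", "cre"))
Description: Implements the GA4GH refget Sequence Collections (seqcol)
    standard: deterministic, content-derived identifiers for collections
    of named sequences (reference genomes, transcriptomes), built from
    RFC 8785 canonical JSON and truncated SHA-512 digests.  Provides
    FASTA ingestion, the attribute-level encoding algorithm with
    inherent/non-inherent schemas, a comparison protocol with Jaccard
    and overlap-proportion scores and set-relationship classification,
    batch analytics for reference-genome compatibility surveys
    (duplicate and subset censuses, pairwise score matrices, sequence
    presence), an HTTP retrieval/comparison API over pluggable stores,
    and a deterministic synthetic-genome fixture generator with planted
    ground-truth relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    base64enc,
    Biostrings,
    curl,
    DBI,
    digest,
    httpuv,
    RSQLite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
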