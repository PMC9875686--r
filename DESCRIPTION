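Package: isoforge
Title: Low-Abundance-Aware Full-Length Isoform Detection from Long-Read RNA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies high-consensus full-length transcript isoforms from
    spliced long-read (nanopore direct RNA-seq) alignments. Implements
    reference-guided splice-junction correction, intron-chain collapsing,
    Gaussian-mixture estimation of transcript start and end sites, and a
    three-step artifact/truncation filter based on junction read support,
    per-read polyadenylation calls and TSS evidence (annotation or CAGE
    peaks). Includes benchmarking metrics (precision/recall against a
    reference annotation, orthogonal TSS/TES support rates, structural
    categories FSM/ISM/NIC/NNC, expression-stratified recall) and a
    synthetic spliced-read simulator with controllable truncation, junction
    jitter and poly(A)-call dropout for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
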