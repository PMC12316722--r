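Package: ringmini
Title: Dosage Typing, Junction Discovery and Breakpoint Statistics for Ring Minichromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes ring minichromosomes from paired-end short-read
    alignments: per-bin read-depth dosage normalized to a non-carrier control
    with classification into six structural types, split-read discovery of
    novel DNA junctions with carrier-exclusivity and pseudo-junction coverage
    filters, greedy contig assembly and in-silico validation across candidate
    junctions, diagnostic-SNP haplotype assignment, and feature-enrichment
    statistics around validated breakpoints against a resampled
    pseudo-breakpoint null. Includes a synthetic cohort generator emitting
    SAM alignments with machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    cluster,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
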