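Package: refscaf
Title: Reference-Guided Contig Stitching, Mate-Pair Scaffolding and Assembly Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for reference-guided assembly of short-read data:
    quality trimming with per-run statistics, stitching of reference-anchored
    read placements into consensus contigs, mate-pair confirmation of contigs,
    greedy path-merging scaffolding with insert-size gap estimates, assembly
    and repeat-content metrics (N50/L50, ungapped length, repeat-family
    coverage), and coalescing of colinear whole-genome alignments into
    syntenic blocks. Includes a deterministic simulator producing a donor
    genome, a diverged reference, fragment and mate-pair read sets with
    decaying quality profiles, and truth tables for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
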