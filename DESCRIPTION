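Package: capssa
Title: Parallel Samplesort-Style Suffix Array and LCP Array Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs the suffix array and longest-common-prefix (LCP)
    array of a byte text (typically DNA) with a samplesort-style algorithm
    built on an LCP-informed mergesort: the text's suffix indices are split
    into uniform subarrays, each is sorted by a merge routine that reuses
    LCP information to skip repeated prefix comparisons, global pivots are
    chosen by oversampling, and the resulting partitions are merged
    independently. Includes a bounded-context variant (suffixes resolved
    only up to their length-k prefixes), comparison-count and working-space
    instrumentation, brute-force oracles, synthetic text generators, FASTA
    ingestion with N-removal and soft-mask removal, a raw little-endian
    on-disk index format with a JSON sidecar, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
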