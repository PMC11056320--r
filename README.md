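# capssa

Samplesort-style construction of the suffix array (SA) and the
longest-common-prefix (LCP) array of a byte text, for people who index
genomes: read aligners, pangenome tooling, and anyone who needs an
enhanced-suffix-array-like index and wants the LCP array to fall out of
construction for free.

## The algorithm

For a text `T` of length `n` (a unique smallest terminator `$` is
appended, so all suffixes are distinct), the suffix array `SA` lists the
start positions of all suffixes in lexicographic order, and the LCP array
`L` stores `L[i] = LCP(T[SA[i]:], T[SA[i-1]:])` with `L[0] = 0`.

Construction runs in four steps:

1. **Local sorting.** The identity permutation of suffix starts is split
   into `p` uniform subarrays; each is sorted by a mergesort whose merge
   step is *LCP-informed*: with `m` the LCP of the last compared pair and
   `l` the run-internal LCP of the advancing side's next suffix, the cases
   `l > m` and `l < m` are decided with zero symbol comparisons, and only
   `l == m` compares symbols — starting at offset `m`. Merges ping-pong
   between two buffer pairs, so total working space stays at `4n` entries.
2. **Pivot selection.** `s` suffixes are sampled from each sorted
   subarray; the `s·p` samples are mergesorted and the `p − 1`
   evenly-spaced order statistics (ranks `s, 2s, …, (p−1)s`) become global
   pivots. With `s = 32 ln n`, every partition has size at most `c·n/p`
   with high probability.
3. **Collation.** Each pivot is located in each subarray by an
   upper-bound binary search with the *simple accelerant* (each probe
   resumes at the smaller of the query's LCPs with the current brackets),
   optionally against a fixed-length pivot prefix. The located boundaries
   cut every subarray into `p` sub-subarrays, which are collated so each
   of the `p` partitions holds one sorted group per subarray.
4. **Partition merging.** Each partition's groups are merged by balanced
   binary recursion with the same LCP-informed merge; LCP values that
   cross partition boundaries are computed directly at the end.

The total number of matching symbol comparisons equals `Σ L[i]` exactly —
an identity this package asserts in its tests — and mismatching
comparisons are `O(n log n)`, so total work is output-sensitive,
`O(n log n + Σ L[i])`.

A **bounded-context** variant resolves suffix order only up to length-`k`
prefixes (ties beyond `k` are declared equal and broken
deterministically), which caps per-pair comparisons at `k`, supports all
pattern queries of length `≤ k`, and speeds up construction dramatically
on repetitive texts.

## Worked example

```r
library(capssa)
idx <- capssa_build("AACTGCGGAT", p = 2)
idx
#> <capssa_index> n = 11, p = 2, full context
#>   SA:  10 0 1 8 5 2 7 4 6 9 3
#>   LCP: 0 0 1 1 0 1 0 1 1 0 1
#>   comparisons: 12 matching, 40 mismatching
#>   peak auxiliary workspace: 63 entries (5.73 n)
```

The SA row says the smallest suffix is the terminator at position 10,
then `AACTGCGGAT$` (position 0), `ACTGCGGAT$` (position 1), `AT$`
(position 8), and so on; the LCP row gives each suffix's shared prefix
length with its predecessor (e.g. `ACTGCGGAT$` shares `A` with
`AACTGCGGAT$`, hence the 1). The matching-comparison count equals
`sum(idx$lcp)` = 12. (On an 11-byte toy input the `O(p²)` pivot metadata
dwarfs `n`; at realistic sizes the workspace instrumentation stays below
`4n` — the test suite asserts this from 10⁴ upward.)

Everything in the pipeline is also exposed piecewise — `merge_sort()`,
`lcp_merge()`, `sample_pivots()`, `locate_pivot()`,
`collate_partitions()`, `merge_partition()`, `fix_boundary_lcps()` — plus
brute-force oracles `brute_force_sa()` / `lcp_from_sa()`, a verifier
`verify_index()`, synthetic generators `generate_text()`, FASTA ingestion
`read_fasta_text()` (N-removal, soft-mask removal, gzip), and a binary
on-disk format `write_index()` / `read_index()` with a JSON sidecar.

## Command line

```sh
Rscript inst/cli/capssa gen --kind periodic -n 100000 --period ACGT -o rep.fa
Rscript inst/cli/capssa build rep.fa -o rep -p 8 --context 64 --verify
Rscript inst/cli/capssa stats rep
Rscript inst/cli/capssa verify rep rep.fa
```

(After installation the script lives at `system.file("cli", "capssa",
package = "capssa")`.)

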