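---
title: "Samplesort suffix array and LCP construction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Samplesort suffix array and LCP construction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capssa)
```

## The problem and the model

A suffix array over a genome-scale text, together with its LCP array, is
the workhorse index behind enhanced-suffix-array pattern matching, seed
finding in read aligners, and many string-processing pipelines. This
package constructs both with a samplesort-style decomposition whose
comparison kernel is an LCP-informed merge: every suffix comparison
happens inside a merge of two sorted runs (or inside a pivot binary
search), and each run carries its LCP array so that comparisons of
already-known common prefixes are never repeated.

The merge invariant is the whole trick. Let `m` be the LCP of the last
compared pair and let `l` be the run-internal LCP between the advancing
side's next suffix and the suffix just emitted. Then:

* `l > m` — the next suffix still agrees with the emitted one beyond the
  point where the other side diverged, so it precedes the other side's
  head; emit it with output LCP `l`. No symbols read.
* `l < m` — the other side's head agrees with the emitted suffix further
  than the next suffix does, so the other head comes first; emit it with
  output LCP `m`, and set `m = l`. No symbols read.
* `l == m` — genuinely unknown; compare symbol-by-symbol starting at
  offset `m` and set `m` to the new pair LCP.

When a run is depleted, the other run's remainder is copied, the first
copied entry taking LCP `m`. Because a new `m` produced by a case-3
comparison is always eventually deposited into the output LCP array, and
per-suffix LCP values never decrease while winding up the merge tree, the
total count of *matching* symbol comparisons over the whole construction
equals the sum of the final LCP array exactly. The test suite asserts
this identity, not just the asymptotic bound, for single-partition
builds, where the identity is exact; with more partitions the pivot
machinery adds its own (lower-order) comparisons on top.

## Pipeline and parameters

`capssa_build(text, p, s, k, prefix_limit, seed, workers)`:

* `p` — partition/subproblem count. Default
  `min(workers, max(1, n/4096))`, i.e. subproblems of a few thousand
  suffixes per worker; any value up to `n` is accepted (clamped with a
  warning above that). The output is identical for every `p`.
* `s` (sampling factor, default 64) — candidate pivots drawn uniformly
  without replacement from each sorted subarray. The balance guarantee
  (`max partition ≤ c·n/p` with high probability) kicks in at
  `s = 32 ln n`; 64 is a practical default for the moderate `p` this
  package targets. `s` is clamped to the shortest subarray so the
  evenly-spaced ranks `s, 2s, …, (p−1)s` are always defined.
* `k` (context bound, symbols; 0 = unbounded) — suffixes agreeing on `k`
  symbols are declared tied. Ties are broken deterministically (merge
  takes the left input first; pivot search sends the whole tie block to
  one side), so bounded-context output is still reproducible. Reported
  LCP values are capped at `k`, which keeps the LCP array meaningful for
  queries of length ≤ `k`; whenever `k ≥ n` the code path degenerates to
  the unbounded one and the output is bit-identical to a full-context
  build.
* `prefix_limit` (0 = unlimited) — pivot binary searches may compare only
  a fixed-length pivot prefix. A run suffix matching the entire truncated
  prefix counts as *greater*, including the pivot's own occurrence, so
  the located boundary is the start of the pivot-prefix block in every
  subarray and partitions remain contiguous ranges of the global order —
  that is why any `prefix_limit ≥ 1` still yields an exact SA, at the
  price of less balanced partitions. With an untruncated search the
  boundary is instead the upper bound (insertion point *after* the pivot
  itself). The default is unlimited.
* `seed` — drives pivot sampling only. Draws are made run by run under a
  locally-set RNG seed (the caller's RNG state is untouched), and the
  effective factor and seed are echoed in the on-disk sidecar.
* `workers` — a parallelism *contract*, not a primitive: subarray sorts
  and partition merges are declared independent tasks, the serial
  schedule implemented here is the reference, and any parallel schedule
  must be bit-identical. `workers` therefore never changes the output
  (the suite checks 1 vs 4); it only feeds the default for `p`.

The first comparison of each merge initialises `m = 0` and compares from
offset 0. The symmetric merge cases (when the right-hand run emitted
last) mirror the three cases above with the roles of the runs exchanged;
both directions are implemented explicitly. Mergesort recursion is pure
(no small-run insertion cutoff): a cutoff with a different comparison
pattern would break the exact accounting identity that the tests pin
down, and the measured benefit in this setting did not justify a second
code path.

## Working space

Merging ping-pongs between two position buffers and two LCP buffers of
length `n`, reused across all recursion levels — four `n`-entry arrays in
total, two of which are returned as the SA and LCP. The package tracks
*auxiliary* workspace — every entry allocated beyond the two returned
arrays: the two scratch arrays (`2n`), pivot/boundary/layout metadata
(`O(p²)`), and the pivot-sample sort, which is placed inside the free
scratch arrays whenever `2·s·p ≤ n` and separately allocated (and
counted) otherwise. For any realistic configuration the metadata is
lower-order and the tracked peak stays below `4n` entries; the suite
asserts the `4n` bound on texts from 10⁴ to 10⁵ across random, periodic,
unary and Fibonacci inputs. On toy inputs where `p²` rivals `n` (say
`p = 11` on an 11-symbol text) the metadata dominates and the bound is
not meaningful, which is a statement about constant factors, not about
the algorithm's linear-space behaviour.

## Oracles, verification, and what the tests show

The brute-force reference path shares no code with the pipeline:
`brute_force_sa()` renders each byte as two hex digits (so C-locale
string order equals byte order, and the interior terminator byte stays
representable) and sorts all suffix strings; `lcp_from_sa()` compares
adjacent suffixes byte-wise. In bounded-context mode the oracle breaks
ties by ascending start position — a documented convention that makes
*its* output deterministic; the pipeline's bounded output is validated as
*a* valid k-order by `verify_index()` rather than by bit-comparison,
since any order within a tie class is correct.

The synthetic generator covers four families: i.i.d. uniform DNA (mean
LCP grows like `log n` — the benign case), periodic motif repetition and
the unary text (mean LCP of order `n` — the pathological, highly
repetitive case; the unary text additionally has the closed-form LCP sum
`m(m−1)/2` used to pin the accounting test), and Fibonacci words (a
standard high-LCP stress family with non-trivial structure). These probe
ordering logic and comparison accounting well, but i.i.d. and purely
periodic texts do not reproduce the long-range, partially repetitive
structure of real genomes, so passing tests say nothing quantitative
about wall-clock performance on real data — correctness properties,
determinism, the accounting identity and the space contract do carry
over, since none of them depend on the input distribution.

Problem sizes used by the suite — 200 random texts up to `n = 2000`
against the oracle (for every `p` in {1, 2, 3, 8} crossed with pivot
prefix limits {1, 16, ∞}), balance at `n = 10⁵` with `p = 16` over 20
seeds, bounded-context behaviour at `n = 10⁵` — were chosen so the whole
suite exercises every guarantee at the scale where it is stated while
remaining a coffee-break run on one core.

## Numerical and degenerate-input choices

* Coordinates are 0-based, intervals half-open, `L[0] = 0` by convention
  (the first SA entry has no predecessor).
* The terminator is an explicit appended byte, default `0x00`, required
  to be strictly smaller than every text byte; inputs already containing
  it are rejected rather than remapped, so round-trips are exact.
* `suffix_compare()`'s `skip` argument is trusted, not re-verified —
  re-checking would destroy the cost contract that the merge relies on; a
  debug flag on `lcp_merge()` re-validates whole runs for tests.
* Comparison counters are accumulated in doubles (they exceed 2³² on
  repetitive 10⁵-symbol texts); positions are 32-bit internally, and the
  on-disk format offers 4- or 8-byte little-endian words with an
  overflow check and an auto mode.
* Multi-record FASTA is concatenated with **no** separators — suffixes
  may span record joins, as when indexing a whole genome as one text;
  record offsets are kept in the sidecar for provenance. `drop_n`
  removes every `N` (the simplest faithful version of dropping
  unresolved assembly runs; the removed count is reported), `unmask`
  uppercases soft-masked regions.
* An empty FASTA errors; an empty text still indexes (the terminator
  alone, `n = 1`).

## Known limitations

Worst-case work is quadratic on adversarial texts (it is output-sensitive
in `Σ L[i]`); the bounded-context mode exists precisely to cap that on
repetitive inputs. Positions are 32-bit in memory, so texts beyond 2³¹
symbols are out of scope for this implementation even though the disk
format already supports 8-byte entries. Pairwise merging only — no
multiway LCP merge — and pivot search does not use LCP-interval-tree
acceleration; both are deliberate simplicity choices.
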