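#' Sample global pivots from sorted subarrays
#'
#' Draws `s` suffixes uniformly without replacement from each of the `p`
#' sorted runs (seeded, reproducible: draws are made run by run in run
#' order under a locally-set seed), sorts the `s * p` samples with
#' [merge_sort()], and selects the `p - 1` evenly-spaced pivots at 0-based
#' ranks `s, 2s, ..., (p-1)s` of the sorted samples.
#'
#' @param runs List of `p` non-empty `sorted_run` objects.
#' @param s Sampling factor; values larger than the shortest run are
#'   clamped (with a warning) so ranks stay well-defined across runs.
#' @param seed Integer seed for the draws.
#' @inheritParams lcp_merge
#' @return An object of class `pivot_set`: list with `pivots` (0-based
#'   suffix positions, strictly increasing as suffixes), `s` (effective
#'   sampling factor) and `seed`.
#' @export
sample_pivots <- function(runs, s, seed, text, k = NULL, stats = NULL) {
  text <- as_text(text)
  p <- length(runs)
  if (p <= 1L)
    return(structure(list(pivots = integer(0), s = as.integer(s),
                          seed = as.integer(seed)), class = "pivot_set"))
  lens <- vapply(runs, function(r) length(r$positions), integer(1))
  stopifnot(all(lens >= 1L))
  s_eff <- as.integer(min(s, min(lens)))
  if (s_eff < s)
    warning(sprintf("sampling factor clamped from %d to %d (shortest run)",
                    as.integer(s), s_eff))
  idx <- with_seed(seed, lapply(lens, function(m) sort(sample.int(m, s_eff))))
  samples <- unlist(lapply(seq_len(p), function(r) {
    runs[[r]]$positions[idx[[r]]]
  }))
  sorted <- merge_sort(samples, text, k = k, stats = stats)
  pivots <- sorted$positions[(1:(p - 1L)) * s_eff + 1L]
  structure(list(pivots = as.integer(pivots), s = s_eff,
                 seed = as.integer(seed)), class = "pivot_set")
}

#' Locate a pivot suffix in a sorted run
#'
#' Upper-bound binary search: returns the smallest 0-based index whose
#' suffix compares greater than the pivot, i.e. the last position at which
#' the pivot could be inserted without breaking the run's order. The
#' search can be restricted to a fixed-length prefix of the pivot
#' (`prefix_limit`); a run suffix that matches the whole truncated prefix
#' and extends beyond it counts as greater, so the returned boundary is
#' the start of the pivot-prefix block in every run and partitions remain
#' contiguous ranges of the full order. Each probe resumes comparison at
#' the smaller of the LCPs of the pivot with the current lo/hi brackets
#' (the simple accelerant); no run LCP array is consulted.
#'
#' @param run A `sorted_run`.
#' @param v 0-based start position of the pivot suffix.
#' @param prefix_limit Positive prefix length, or `NULL`/`0`/`Inf` for the
#'   full pivot suffix.
#' @inheritParams lcp_merge
#' @return 0-based insertion index in `[0, length(run)]`.
#' @export
locate_pivot <- function(run, v, text, prefix_limit = NULL, k = NULL,
                         stats = NULL) {
  text <- as_text(text)
  res <- cpp_locate_pivot(text$data, run$positions, as.integer(v),
                          norm_prefix_limit(prefix_limit), norm_k(k))
  stats_add(stats, res)
  res$idx
}

#' Collate sub-subarrays into samplesort partitions
#'
#' Locates every pivot in every sorted run, derives the cumulative
#' partition layout `C_0 ... C_p`, and rearranges positions and LCP values
#' so that partition `j` occupies `[C_j, C_{j+1})` and holds, from every
#' run in run order, exactly its `j`-th sub-subarray. Each sub-subarray
#' keeps its run-local LCP slice except that its first entry is reset to 0
#' (its predecessor changed).
#'
#' @param runs List of `p` `sorted_run`s jointly covering all `n` positions.
#' @param pivots A `pivot_set` (or integer vector of pivot positions).
#' @inheritParams locate_pivot
#' @return List with `layout` (list `cumulative` = `C_0..C_p`,
#'   `group_bounds` = per-partition absolute group offsets, each of length
#'   `p + 1`), `positions` and `lcps` (the rearranged arrays).
#' @export
collate_partitions <- function(runs, pivots, text, prefix_limit = NULL,
                               k = NULL, stats = NULL) {
  text <- as_text(text)
  n <- text$n
  piv <- if (inherits(pivots, "pivot_set")) pivots$pivots else as.integer(pivots)
  p <- length(piv) + 1L
  nr <- length(runs)
  # bounds[r, j]: insertion index of pivot j in run r
  bounds <- matrix(0L, nrow = nr, ncol = length(piv))
  for (r in seq_len(nr))
    for (j in seq_along(piv))
      bounds[r, j] <- locate_pivot(runs[[r]], piv[j], text, prefix_limit, k,
                                   stats)
  lens <- vapply(runs, function(x) length(x$positions), integer(1))
  starts <- function(r, j) if (j == 1L) 0L else bounds[r, j - 1L]
  ends <- function(r, j) if (j == p) lens[r] else bounds[r, j]
  sizes <- vapply(seq_len(p), function(j)
    sum(vapply(seq_len(nr), function(r) ends(r, j) - starts(r, j),
               integer(1))), integer(1))
  C <- c(0L, cumsum(sizes))
  if (C[p + 1L] != sum(lens))
    stop("internal consistency error: partition sizes do not sum to n",
         call. = FALSE)
  positions <- integer(sum(lens))
  lcps <- integer(sum(lens))
  group_bounds <- vector("list", p)
  for (j in seq_len(p)) {
    out <- C[j]
    gb <- integer(nr + 1L)
    gb[1L] <- out
    for (r in seq_len(nr)) {
      sgs <- starts(r, j)
      sge <- ends(r, j)
      if (sge > sgs) {
        span <- (sgs + 1L):sge
        positions[(out + 1L):(out + sge - sgs)] <- runs[[r]]$positions[span]
        lv <- runs[[r]]$lcps[span]
        lv[1L] <- 0L
        lcps[(out + 1L):(out + sge - sgs)] <- lv
        out <- out + sge - sgs
      }
      gb[r + 1L] <- out
    }
    group_bounds[[j]] <- gb
  }
  list(layout = list(cumulative = C, group_bounds = group_bounds),
       positions = positions, lcps = lcps)
}

#' Merge the sorted groups of one partition
#'
#' Balanced binary recursive merge of a partition's contiguous sorted
#' groups (the sub-subarrays contributed by each run): the group list is
#' split in half, each half merged recursively, and the halves merged with
#' [lcp_merge()], ping-ponging between two buffer pairs. Empty groups are
#' permitted (a pivot need not split every run).
#'
#' @param groups List of `sorted_run`s, in their collated (contiguous)
#'   order.
#' @inheritParams lcp_merge
#' @return The fully merged `sorted_run`.
#' @export
merge_partition <- function(groups, text, k = NULL, stats = NULL) {
  text <- as_text(text)
  if (length(groups) == 1L) return(groups[[1L]])
  pos <- unlist(lapply(groups, `[[`, "positions"))
  lcp <- unlist(lapply(groups, `[[`, "lcps"))
  if (is.null(pos)) pos <- integer(0)
  if (is.null(lcp)) lcp <- integer(0)
  gofs <- c(0L, cumsum(vapply(groups, function(g) length(g$positions),
                              integer(1))))
  res <- cpp_merge_partition(text$data, as.integer(pos), as.integer(lcp),
                             gofs, norm_k(k))
  stats_add(stats, res)
  sorted_run(res$pos, res$lcp)
}
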