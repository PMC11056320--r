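#' Sorted run of suffixes with its LCP array
#'
#' A contiguous block of suffix start positions in sorted order together
#' with its run-internal LCP values (`lcps[1]` is 0 by convention: the
#' first element of a run has no predecessor inside the run).
#'
#' @param positions Integer vector of 0-based suffix start positions.
#' @param lcps Integer vector of the same length; defaults to the pairwise
#'   LCPs being supplied by the caller.
#' @return An object of class `sorted_run`.
#' @export
sorted_run <- function(positions, lcps) {
  positions <- as.integer(positions)
  lcps <- as.integer(lcps)
  stopifnot(length(positions) == length(lcps))
  if (length(lcps) && lcps[1L] != 0L)
    stop("invalid input: a sorted run's first LCP entry must be 0", call. = FALSE)
  structure(list(positions = positions, lcps = lcps), class = "sorted_run")
}

#' @export
print.sorted_run <- function(x, ...) {
  cat(sprintf("<sorted_run> %d suffixes\n", length(x$positions)))
  cat("  positions:", paste(head(x$positions, 20), collapse = " "),
      if (length(x$positions) > 20) "..." else "", "\n")
  cat("  lcps:     ", paste(head(x$lcps, 20), collapse = " "),
      if (length(x$lcps) > 20) "..." else "", "\n")
  invisible(x)
}

#' Symbol-comparison counters
#'
#' Mutable counter pair recording the number of matching (equal) and
#' mismatching (unequal) symbol comparisons performed by the merge
#' machinery. The matching count of a complete mergesort of all suffixes
#' equals the sum of the final LCP array exactly, which is the accounting
#' identity behind the algorithm's output-sensitive work bound.
#'
#' @return An environment of class `merge_stats` with numeric fields
#'   `matching` and `mismatching`.
#' @examples
#' st <- merge_stats()
#' st$matching
#' @export
merge_stats <- function() {
  e <- new.env(parent = emptyenv())
  e$matching <- 0
  e$mismatching <- 0
  class(e) <- "merge_stats"
  e
}

#' @export
print.merge_stats <- function(x, ...) {
  cat(sprintf("<merge_stats> matching = %.0f, mismatching = %.0f\n",
              x$matching, x$mismatching))
  invisible(x)
}

stats_add <- function(stats, res) {
  if (!is.null(stats)) {
    stopifnot(inherits(stats, "merge_stats"))
    stats$matching <- stats$matching + res$matching
    stats$mismatching <- stats$mismatching + res$mismatching
  }
  invisible(stats)
}

check_run_sorted <- function(run, text, k) {
  pos <- run$positions
  if (length(pos) < 2L) return(invisible(TRUE))
  for (i in 2:length(pos)) {
    cmp <- suffix_compare(text, pos[i - 1L], pos[i], 0L, k)
    ok <- cmp$relation == "less" || (norm_k(k) > 0L && cmp$relation == "tie")
    if (!ok)
      stop("invalid input: run is not sorted at index ", i - 1L, call. = FALSE)
    if (cmp$lcp != run$lcps[i])
      stop("invalid input: run LCP value wrong at index ", i - 1L, call. = FALSE)
  }
  invisible(TRUE)
}

#' LCP-informed merge of two sorted runs
#'
#' Merges two sorted runs of suffixes into one, producing the merged LCP
#' array alongside. The classic merge is modified so that, with `m` the LCP
#' of the last compared pair and `l` the run-internal LCP of the advancing
#' side's next element, the cases `l > m` and `l < m` are resolved with no
#' symbol comparison at all, and the case `l == m` resumes comparison at
#' offset `m`. When one run is depleted the remainder of the other is
#' copied, the first copied entry receiving LCP `m`. Under a context bound
#' `k`, ties (shared prefix of length `k`) take the `x`-side element first,
#' so output is deterministic.
#'
#' @param x,y `sorted_run` objects over `text`.
#' @param text A `capssa_text`.
#' @param k Context bound; `NULL` or `0` for unbounded.
#' @param stats Optional [merge_stats()] accumulator.
#' @param debug If `TRUE`, re-verify that inputs are sorted runs (costly;
#'   defeats the comparison-cost contract, intended for tests only).
#' @return The merged `sorted_run`.
#' @export
lcp_merge <- function(x, y, text, k = NULL, stats = NULL, debug = FALSE) {
  text <- as_text(text)
  if (isTRUE(debug)) {
    check_run_sorted(x, text, k)
    check_run_sorted(y, text, k)
  }
  res <- cpp_lcp_merge(text$data, x$positions, x$lcps, y$positions, y$lcps,
                       norm_k(k))
  stats_add(stats, res)
  sorted_run(res$pos, res$lcp)
}

#' Mergesort of suffix positions with LCP output
#'
#' Sorts a set of suffix start positions with a mergesort whose merge step
#' is [lcp_merge()], producing the run's LCP array as a byproduct. The
#' implementation ping-pongs between two buffer pairs across recursion
#' levels, so the auxiliary storage stays at two extra entry buffers of the
#' input length.
#'
#' @param positions Integer vector of distinct 0-based suffix positions
#'   (any order). An empty input yields an empty run.
#' @inheritParams lcp_merge
#' @return A `sorted_run` over the same positions.
#' @examples
#' merge_sort(c(3, 9), build_text("AACTGCGGAT"))
#' @export
merge_sort <- function(positions, text, k = NULL, stats = NULL) {
  text <- as_text(text)
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(sorted_run(integer(0), integer(0)))
  res <- cpp_merge_sort(text$data, positions, norm_k(k))
  stats_add(stats, res)
  sorted_run(res$pos, res$lcp)
}
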