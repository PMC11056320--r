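#' Construction configuration
#'
#' Bundles the tunable parameters of the samplesort pipeline.
#'
#' @param p Partition (subproblem) count. `NULL` selects
#'   `min(workers, max(1, n %/% 4096))` at build time.
#' @param s Sampling factor: candidate pivots drawn per subarray before the
#'   evenly-spaced global pivots are selected. Default 64.
#' @param k Context bound in symbols; 0 (default) builds the full-context
#'   index, `k > 0` resolves suffix order only up to length-`k` prefixes.
#' @param prefix_limit Pivot-prefix length used during binary-search pivot
#'   placement; 0 (default) searches with the full pivot suffix.
#' @param seed Seed for pivot sampling.
#' @param width On-disk integer width in bytes: 4, 8, or `"auto"` (4 while
#'   `n < 2^32`).
#' @param workers Parallelism hint. Subarray sorts and partition merges are
#'   independent tasks; the serial schedule used here is the reference and
#'   any parallel schedule must be bit-identical, so `workers` never
#'   changes the output.
#' @return A list of class `capssa_config`.
#' @export
capssa_config <- function(p = NULL, s = 64L, k = 0L, prefix_limit = 0L,
                          seed = 1L, width = "auto", workers = 1L) {
  stopifnot(is.null(p) || p >= 1, s >= 1, norm_k(k) >= 0, workers >= 1)
  structure(list(p = if (is.null(p)) NULL else as.integer(p),
                 s = as.integer(s), k = norm_k(k),
                 prefix_limit = norm_prefix_limit(prefix_limit),
                 seed = as.integer(seed), width = width,
                 workers = as.integer(workers)),
            class = "capssa_config")
}

#' Build the suffix array and LCP array
#'
#' End-to-end construction: the identity permutation of suffix starts is
#' split into `p` uniform subarrays, each sorted by the LCP-informed
#' mergesort; global pivots are sampled from the sorted subarrays; each
#' pivot is located in each subarray by accelerated binary search; the
#' resulting sub-subarrays are collated into `p` partitions which are
#' merged independently; finally the LCP values crossing partition
#' boundaries are computed. Output is identical for any worker count and,
#' at full context, equals the brute-force oracle. Symbol comparisons and
#' peak auxiliary workspace (entries beyond the returned arrays) are
#' tracked throughout.
#'
#' @param text A `capssa_text` (or character/raw coerced via [as_text()]).
#' @param config A [capssa_config()]; individual fields can be overridden
#'   with `...`.
#' @param ... Named [capssa_config()] fields overriding `config`.
#' @return An object of class `capssa_index`: list with `sa` and `lcp`
#'   (integer vectors, 0-based positions / symbol counts), `n`, `stats`
#'   (matching and mismatching symbol-comparison counts), `layout`
#'   (cumulative partition offsets `C_0..C_p`), `peak_aux` (peak auxiliary
#'   entries), and the effective `config`.
#' @examples
#' idx <- capssa_build("AACTGCGGAT", p = 2)
#' idx$sa   # 10 0 1 8 5 2 7 4 6 9 3
#' idx$lcp  # 0 0 1 1 0 1 0 1 1 0 1
#' @export
capssa_build <- function(text, config = capssa_config(), ...) {
  text <- as_text(text)
  n <- text$n
  dots <- list(...)
  if (length(dots)) {
    cfg <- unclass(config)
    cfg[names(dots)] <- dots
    config <- do.call(capssa_config, cfg)
  }
  p <- config$p
  if (is.null(p)) p <- min(config$workers, max(1L, n %/% 4096L))
  p <- as.integer(p)
  if (p > n) {
    warning(sprintf("p = %d exceeds n = %d; clamped to n", p, n))
    p <- n
  }
  samples <- list()
  s_eff <- config$s
  if (p > 1L) {
    off <- as.integer((as.numeric(0:p) * n) %/% p)  # same split as the C++ side
    lens <- diff(off)
    s_eff <- as.integer(min(config$s, min(lens)))
    if (s_eff < config$s)
      warning(sprintf("sampling factor clamped from %d to %d (shortest run)",
                      config$s, s_eff))
    samples <- with_seed(config$seed,
                         lapply(lens, function(m) sort(sample.int(m, s_eff))))
  }
  res <- cpp_construct(text$data, p, config$k, config$prefix_limit, samples)
  eff <- config
  eff$p <- p
  eff$s <- s_eff
  structure(
    list(sa = res$sa, lcp = res$lcp, n = n,
         stats = list(matching = res$matching,
                      mismatching = res$mismatching),
         layout = list(cumulative = res$C),
         peak_aux = res$peak_aux,
         config = eff,
         checksum = cpp_fnv64(text$data)),
    class = "capssa_index")
}

#' @export
print.capssa_index <- function(x, ...) {
  cat(sprintf("<capssa_index> n = %d, p = %d, %s context\n", x$n,
              x$config$p,
              if (x$config$k > 0) sprintf("k = %d bounded", x$config$k)
              else "full"))
  cat(sprintf("  SA:  %s%s\n", paste(head(x$sa, 15), collapse = " "),
              if (x$n > 15) " ..." else ""))
  cat(sprintf("  LCP: %s%s\n", paste(head(x$lcp, 15), collapse = " "),
              if (x$n > 15) " ..." else ""))
  cat(sprintf("  comparisons: %.0f matching, %.0f mismatching\n",
              x$stats$matching, x$stats$mismatching))
  cat(sprintf("  peak auxiliary workspace: %.0f entries (%.2f n)\n",
              x$peak_aux, x$peak_aux / x$n))
  invisible(x)
}

#' @export
summary.capssa_index <- function(object, ...) {
  st <- lcp_stats(object$lcp)
  cat(sprintf("<capssa_index> n = %d\n", object$n))
  cat(sprintf("  LCP mean %.3f, sd %.3f, max %d\n",
              st["mean"], st["sd"], as.integer(st["max"])))
  invisible(st)
}

#' Recompute LCP values that cross partition boundaries
#'
#' Per-partition merges produce LCP arrays that are correct within each
#' partition; the value at each partition boundary `C_j` refers to a pair
#' that straddles two partitions and is computed at the end by a direct
#' suffix comparison (capped at `k`). Entry 0 is always 0.
#'
#' @inheritParams lcp_from_sa
#' @param lcp Integer LCP array, internally correct per partition.
#' @param layout Layout list with `cumulative` offsets `C_0..C_p` (as in a
#'   `capssa_index`).
#' @return The corrected LCP array.
#' @export
fix_boundary_lcps <- function(text, sa, lcp, layout, k = NULL) {
  text <- as_text(text)
  n <- text$n
  C <- layout$cumulative
  lcp <- as.integer(lcp)
  lcp[1L] <- 0L
  p <- length(C) - 1L
  if (p >= 2L) {
    for (j in 2:p) {
      b <- C[j]
      if (b > 0L && b < n)
        lcp[b + 1L] <- suffix_compare(text, sa[b], sa[b + 1L], 0L, k)$lcp
    }
  }
  lcp
}

#' Verify a suffix array and LCP array
#'
#' Checks that `sa` is a permutation of `[0, n)`, that consecutive
#' suffixes are in (k-bounded) lexicographic order, and that every LCP
#' value equals the pairwise (capped) LCP. In bounded-context mode an
#' adjacent tie (shared prefix of length `>= k`) is valid in either order.
#'
#' @inheritParams lcp_from_sa
#' @param lcp Integer LCP array to verify.
#' @return List of class `capssa_verification`: flags `is_sorted`,
#'   `is_permutation`, `lcp_ok`, and `first_violation` (0-based index or
#'   `NA`).
#' @export
verify_index <- function(text, sa, lcp, k = NULL) {
  text <- as_text(text)
  n <- text$n
  sa <- as.integer(sa)
  lcp <- as.integer(lcp)
  kk <- norm_k(k)
  rep <- list(is_sorted = TRUE, is_permutation = TRUE, lcp_ok = TRUE,
              first_violation = NA_integer_)
  if (length(sa) != n || !identical(sort(sa), 0:(n - 1L))) {
    rep$is_permutation <- FALSE
    rep$first_violation <- 0L
    class(rep) <- "capssa_verification"
    return(rep)
  }
  if (length(lcp) != n || lcp[1L] != 0L) {
    rep$lcp_ok <- FALSE
    rep$first_violation <- 0L
  }
  if (n >= 2L) {
    for (i in 2:n) {
      cmp <- suffix_compare(text, sa[i - 1L], sa[i], 0L, kk)
      ordered <- cmp$relation == "less" ||
        (kk > 0L && cmp$relation == "tie" && cmp$lcp == kk)
      if (!ordered && rep$is_sorted) {
        rep$is_sorted <- FALSE
        if (is.na(rep$first_violation)) rep$first_violation <- i - 1L
      }
      if (lcp[i] != cmp$lcp && rep$lcp_ok) {
        rep$lcp_ok <- FALSE
        if (is.na(rep$first_violation)) rep$first_violation <- i - 1L
      }
      if (!rep$is_sorted && !rep$lcp_ok) break
    }
  }
  class(rep) <- "capssa_verification"
  rep
}

#' @export
print.capssa_verification <- function(x, ...) {
  ok <- x$is_sorted && x$is_permutation && x$lcp_ok
  cat(sprintf("<verification> %s (sorted: %s, permutation: %s, lcp: %s)\n",
              if (ok) "VALID" else "INVALID",
              x$is_sorted, x$is_permutation, x$lcp_ok))
  if (!ok) cat(sprintf("  first violation at index %d\n", x$first_violation))
  invisible(x)
}

#' Summary moments of an LCP array
#'
#' Population mean, population standard deviation and maximum of the LCP
#' values at indices `1 .. n-1` (the 0-index entry is the conventional 0
#' and is excluded).
#'
#' @param lcp Integer LCP array of length `n >= 2`.
#' @return Named numeric vector `mean`, `sd`, `max`.
#' @examples
#' lcp_stats(capssa_build("AACTGCGGAT")$lcp)  # mean 0.6
#' @export
lcp_stats <- function(lcp) {
  if (length(lcp) < 2L)
    stop("undefined: LCP statistics need n >= 2", call. = FALSE)
  v <- as.numeric(lcp[-1L])
  m <- mean(v)
  c(mean = m, sd = sqrt(mean((v - m)^2)), max = max(v))
}
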