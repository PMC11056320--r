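#' Build an indexed text with an appended terminator
#'
#' Represents the text to be indexed as a raw byte sequence with a unique
#' terminator appended. The terminator must be strictly smaller than every
#' byte of the input so that all suffixes are distinct and the shortest
#' suffix (the terminator alone) sorts first.
#'
#' @param raw The text body, as a raw vector or a single character string
#'   (converted byte-wise). Must not contain the terminator byte.
#' @param terminator A single raw byte, strictly smaller than every byte in
#'   `raw`. Defaults to `0x00`, rendered as `$` when printing.
#' @return An object of class `capssa_text`: a list with `data` (raw bytes
#'   including the terminator), `n` (length including the terminator), and
#'   `alphabet` (sorted distinct bytes present).
#' @examples
#' t <- build_text("AACTGCGGAT")
#' t$n  # 11
#' @export
build_text <- function(raw, terminator = as.raw(0L)) {
  if (is.character(raw)) {
    stopifnot(length(raw) == 1L)
    raw <- charToRaw(raw)
  }
  stopifnot(is.raw(raw), is.raw(terminator), length(terminator) == 1L)
  if (any(raw == terminator))
    stop("invalid input: text contains the terminator byte", call. = FALSE)
  if (length(raw) && as.integer(terminator) >= min(as.integer(raw)))
    stop("invalid input: terminator byte is not smaller than every text byte",
         call. = FALSE)
  data <- c(raw, terminator)
  structure(
    list(data = data,
         n = length(data),
         alphabet = as.raw(sort(unique(as.integer(data)))),
         terminator = terminator),
    class = "capssa_text"
  )
}

#' @rdname build_text
#' @param x Object to convert.
#' @param ... Passed to [build_text()].
#' @export
as_text <- function(x, ...) {
  if (inherits(x, "capssa_text")) return(x)
  build_text(x, ...)
}

#' @export
print.capssa_text <- function(x, ...) {
  body <- x$data[-x$n]
  shown <- if (length(body) > 60) c(head(body, 60)) else body
  txt <- rawToChar(shown[shown >= as.raw(32) & shown <= as.raw(126)])
  cat(sprintf("<capssa_text> n = %d (terminator included), |alphabet| = %d\n",
              x$n, length(x$alphabet)))
  cat(sprintf("  %s%s$\n", txt, if (length(body) > 60) "..." else ""))
  invisible(x)
}

norm_k <- function(k) {
  if (is.null(k) || is.na(k) || k <= 0) 0L else as.integer(k)
}

#' Compare two suffixes, optionally under a bounded context
#'
#' Character-by-character comparison of the suffixes starting at `a` and
#' `b`, resuming after a caller-asserted known common prefix `skip` (which
#' is trusted, not re-verified). With a context bound `k`, suffixes that
#' agree on their first `k` symbols are declared tied and the reported LCP
#' is capped at `k`.
#'
#' @param text A `capssa_text`.
#' @param a,b 0-based suffix start positions.
#' @param skip Known common prefix length to skip (must not exceed the true
#'   LCP of the two suffixes).
#' @param k Context bound; `NULL` or `0` means unbounded.
#' @return A list with `relation` (`"less"`, `"greater"` or `"tie"`), `lcp`
#'   (exact LCP, capped at `k`), and `reads` (symbols read).
#' @examples
#' t <- build_text("AACTGCGGAT")
#' suffix_compare(t, 0, 1)  # less, lcp 1
#' @export
suffix_compare <- function(text, a, b, skip = 0L, k = NULL) {
  text <- as_text(text)
  n <- text$n
  if (a < 0 || a >= n || b < 0 || b >= n)
    stop("bounds error: suffix positions must lie in [0, n)", call. = FALSE)
  res <- cpp_suffix_compare(text$data, as.integer(a), as.integer(b),
                            as.integer(skip), norm_k(k))
  list(relation = c("less", "tie", "greater")[res$rel + 2L],
       lcp = res$lcp,
       reads = res$reads)
}

#' Brute-force suffix array (test oracle)
#'
#' Naive construction: every suffix is materialised and the start positions
#' are sorted byte-wise. This is the independent reference implementation
#' used to validate the samplesort pipeline; it does not share code with
#' it. In bounded-context mode suffixes are compared only on their first
#' `k` symbols and ties are broken by ascending start position, making the
#' oracle output deterministic.
#'
#' @inheritParams suffix_compare
#' @return Integer vector of 0-based suffix start positions in
#'   lexicographic order.
#' @examples
#' brute_force_sa(build_text("AACTGCGGAT"))
#' @export
brute_force_sa <- function(text, k = NULL) {
  text <- as_text(text)
  n <- text$n
  k <- norm_k(k)
  # two lowercase hex digits per byte preserve byte order under C-locale
  # string collation, and keep embedded 0x00 terminators representable
  hx <- paste(sprintf("%02x", as.integer(text$data)), collapse = "")
  starts <- 2L * (0:(n - 1L)) + 1L
  sufs <- if (k > 0L)
    substring(hx, starts, pmin(starts + 2L * k - 1L, 2L * n))
  else
    substring(hx, starts)
  ord <- order(sufs, 0:(n - 1L), method = "radix")
  as.integer(ord - 1L)
}

#' Pairwise LCP array from a suffix array (test oracle)
#'
#' Direct pairwise computation: entry `i` (0-based, `i >= 1`) is the LCP of
#' the suffixes at `sa[i-1]` and `sa[i]`; entry 0 is 0 by convention. LCPs
#' are capped at `k` in bounded-context mode. Implemented with vectorised
#' raw comparisons, independent of the merge pipeline.
#'
#' @inheritParams suffix_compare
#' @param sa Integer vector, a permutation of `0:(n-1)`.
#' @return Integer vector of `n` LCP values.
#' @examples
#' t <- build_text("AACTGCGGAT")
#' lcp_from_sa(t, brute_force_sa(t))
#' @export
lcp_from_sa <- function(text, sa, k = NULL) {
  text <- as_text(text)
  n <- text$n
  k <- norm_k(k)
  sa <- as.integer(sa)
  if (length(sa) != n || !identical(sort(sa), 0:(n - 1L)))
    stop("invalid input: sa is not a permutation of [0, n)", call. = FALSE)
  d <- as.integer(text$data)
  out <- integer(n)
  if (n >= 2L) {
    for (i in 2:n) {
      a <- sa[i - 1L] + 1L
      b <- sa[i] + 1L
      len <- min(n - a, n - b) + 1L
      neq <- which(d[a:(a + len - 1L)] != d[b:(b + len - 1L)])
      l <- if (length(neq)) neq[1L] - 1L else len
      out[i] <- if (k > 0L) min(l, k) else l
    }
  }
  out
}
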