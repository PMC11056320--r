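# Shared fixtures and naive reference helpers, independent of the C++ path.

worked <- list(
  text = "AACTGCGGAT",
  sa = c(10L, 0L, 1L, 8L, 5L, 2L, 7L, 4L, 6L, 9L, 3L),
  lcp = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L)
)

# random text over the first `ab` uppercase letters
rand_text <- function(n, ab = 4L, seed = 1L) {
  generate_text("random", n, alphabet = rawToChar(as.raw(64L + seq_len(ab))),
                seed = seed)
}

# hex rendering of a suffix so string comparison equals byte comparison
suffix_hex <- function(text, pos, limit = Inf) {
  hx <- paste(sprintf("%02x", as.integer(text$data)), collapse = "")
  s <- substring(hx, 2L * pos + 1L)
  if (is.finite(limit)) substr(s, 1L, 2L * limit) else s
}

# naive linear-scan pivot placement mirroring the documented upper-bound
# and truncated-prefix semantics
naive_locate <- function(run, v, text, prefix_limit = Inf, k = Inf) {
  lim <- min(prefix_limit, k, text$n - v)
  truncated <- lim < text$n - v
  pstr <- suffix_hex(text, v, lim)
  gt <- vapply(run$positions, function(u) {
    ustr <- suffix_hex(text, u)
    if (truncated) {
      upre <- substr(ustr, 1L, nchar(pstr))
      upre > pstr || upre == pstr  # matching the truncated prefix => greater
    } else {
      ustr > pstr                  # full suffix comparison; v itself is not
    }
  }, logical(1))
  # upper bound: count of elements not greater than the searched prefix
  sum(!gt)
}

expect_valid_run <- function(run, text, k = NULL) {
  pos <- run$positions
  if (length(pos) < 2L) return(invisible(TRUE))
  for (i in 2:length(pos)) {
    cmp <- suffix_compare(text, pos[i - 1L], pos[i], 0L, k)
    expect_true(cmp$relation == "less" ||
                  (!is.null(k) && k > 0 && cmp$relation == "tie"))
    expect_identical(run$lcps[i], as.integer(cmp$lcp))
  }
  invisible(TRUE)
}
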