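#' Generate synthetic texts
#'
#' Deterministic (seeded) text generators covering the input classes that
#' matter for suffix sorting: `random` draws i.i.d. uniform symbols from
#' the alphabet (low mean LCP, like non-repetitive genome sequence),
#' `periodic` repeats a motif (mean LCP on the order of `n`, the
#' pathological highly-repetitive case), `unary` repeats one symbol (the
#' adversarial extreme with closed-form LCP sum `m(m-1)/2` for `m`
#' symbols), and `fibonacci` builds the standard high-LCP Fibonacci-word
#' stress family over two symbols.
#'
#' @param kind One of `"random"`, `"periodic"`, `"unary"`, `"fibonacci"`.
#' @param n Total text length, terminator included (so the body has
#'   `n - 1` symbols).
#' @param alphabet Character vector (or raw) of symbols for `random`;
#'   default DNA `A C G T`.
#' @param period Motif string for `periodic`, e.g. `"ACGT"`.
#' @param seed Integer seed (used by `random` only, but accepted for all).
#' @return A `capssa_text` of length `n`.
#' @examples
#' generate_text("unary", 6)          # AAAAA$
#' generate_text("random", 50, seed = 7)
#' @export
generate_text <- function(kind = c("random", "periodic", "unary", "fibonacci"),
                          n, alphabet = c("A", "C", "G", "T"),
                          period = "ACGT", seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("invalid generator input: n must be >= 1", call. = FALSE)
  m <- n - 1L
  body <- switch(kind,
    random = {
      if (is.character(alphabet))
        alphabet <- charToRaw(paste(alphabet, collapse = ""))
      if (!length(alphabet)) stop("invalid generator input: empty alphabet", call. = FALSE)
      with_seed(seed, alphabet[sample.int(length(alphabet), m, replace = TRUE)])
    },
    periodic = {
      if (!nchar(period)) stop("invalid generator input: empty motif", call. = FALSE)
      motif <- charToRaw(period)
      rep_len(motif, m)
    },
    unary = rep(charToRaw("A"), m),
    fibonacci = {
      a <- charToRaw("A")
      b <- charToRaw("B")
      prev <- a            # F1
      cur <- c(a, b)       # F2 = F1 F0-style seed pair
      while (length(cur) < m) {
        nxt <- c(cur, prev)
        prev <- cur
        cur <- nxt
      }
      cur[seq_len(m)]
    })
  if (m == 0L) body <- raw(0)
  build_text(body)
}
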