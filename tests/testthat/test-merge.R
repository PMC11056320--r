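test_that("lcp_merge handles the case analysis and depletion copying", {
  t <- build_text(worked$text)
  st <- merge_stats()
  # basic merge with a mid-insertion
  z <- lcp_merge(sorted_run(c(0, 1), c(0, 1)), sorted_run(8, 0), t, stats = st)
  expect_identical(z$positions, c(0L, 1L, 8L))
  expect_identical(z$lcps, c(0L, 1L, 1L))
  # case l_x > m keeps the x side streaming, then depletion copy
  z <- lcp_merge(sorted_run(c(5, 2), c(0, 1)), sorted_run(7, 0), t)
  expect_identical(z$positions, c(5L, 2L, 7L))
  expect_identical(z$lcps, c(0L, 1L, 0L))
  # case l_x < m emits the y side with no symbol comparison
  z <- lcp_merge(sorted_run(c(4, 9), c(0, 0)), sorted_run(6, 0), t)
  expect_identical(z$positions, c(4L, 6L, 9L))
  expect_identical(z$lcps, c(0L, 1L, 0L))
  # empty y is the identity
  x <- sorted_run(c(5, 2), c(0, 1))
  expect_identical(lcp_merge(x, sorted_run(integer(0), integer(0)), t), x)
  # debug mode rejects an unsorted input
  expect_error(
    lcp_merge(sorted_run(c(2, 5), c(0, 0)), sorted_run(7, 0), t, debug = TRUE),
    "not sorted")
})

test_that("cheap merge cases perform zero symbol comparisons", {
  t <- build_text(worked$text)
  # [4,9] vs [6]: first comparison costs reads, the l_x < m step costs none
  st <- merge_stats()
  lcp_merge(sorted_run(c(4, 9), c(0, 0)), sorted_run(6, 0), t, stats = st)
  first <- suffix_compare(t, 4, 6)
  expect_identical(st$matching + st$mismatching, first$reads)
})

test_that("merge_sort reproduces known runs including the worked example", {
  t <- build_text(worked$text)
  z <- merge_sort(c(3, 9), t)
  expect_identical(z$positions, c(9L, 3L))
  expect_identical(z$lcps, c(0L, 1L))
  z <- merge_sort(worked$sa, t)   # any input permutation sorts identically
  expect_identical(z$positions, worked$sa)
  expect_identical(z$lcps, worked$lcp)
  z <- merge_sort(0:10, t)
  expect_identical(z$positions, worked$sa)
  expect_identical(merge_sort(6, t), sorted_run(6L, 0L))
  expect_identical(merge_sort(integer(0), t),
                   sorted_run(integer(0), integer(0)))
})

test_that("merge_sort agrees with the brute-force oracle on random texts", {
  for (seed in 1:40) {
    t <- rand_text(sample(2:300, 1), ab = sample(2:8, 1), seed = seed)
    run <- merge_sort(sample(0:(t$n - 1L)), t)
    expect_identical(run$positions, brute_force_sa(t))
    expect_identical(run$lcps, lcp_from_sa(t, run$positions))
  }
})

test_that("per-suffix LCP values never decrease across merge levels", {
  # bottom-up mergesort over lcp_merge, tracking each suffix's LCP with its
  # predecessor in its current instance (0 for a first element)
  per_suffix <- function(runs) {
    v <- integer(0)
    nm <- integer(0)
    for (r in runs) {
      v <- c(v, r$lcps)
      nm <- c(nm, r$positions)
    }
    v[order(nm)]
  }
  for (case in list(rand_text(200, 4, seed = 3),
                    generate_text("periodic", 150, period = "ACG"),
                    generate_text("fibonacci", 180))) {
    runs <- lapply(0:(case$n - 1L), function(i) sorted_run(i, 0L))
    prev <- per_suffix(runs)
    while (length(runs) > 1L) {
      nxt <- list()
      i <- 1L
      while (i + 1L <= length(runs)) {
        nxt[[length(nxt) + 1L]] <- lcp_merge(runs[[i]], runs[[i + 1L]], case)
        i <- i + 2L
      }
      if (i == length(runs)) nxt[[length(nxt) + 1L]] <- runs[[i]]
      runs <- nxt
      cur <- per_suffix(runs)
      expect_true(all(cur >= prev))
      prev <- cur
    }
    expect_identical(runs[[1]]$positions, brute_force_sa(case))
  }
})

test_that("matching comparisons of a full mergesort equal the LCP sum", {
  for (case in list(rand_text(400, 4, seed = 11),
                    rand_text(257, 2, seed = 12),
                    generate_text("periodic", 300, period = "ACGT"),
                    generate_text("unary", 200))) {
    st <- merge_stats()
    run <- merge_sort(0:(case$n - 1L), case, stats = st)
    expect_identical(st$matching, sum(as.numeric(run$lcps)))
    expect_lte(st$mismatching, case$n * ceiling(log2(case$n)))
  }
})

test_that("bounded-context merge caps LCPs, ties stable-left, and stays valid", {
  t <- generate_text("periodic", 400, period = "ACGT")
  k <- 8L
  st <- merge_stats()
  run <- merge_sort(0:(t$n - 1L), t, k = k, stats = st)
  expect_true(all(run$lcps <= k))
  expect_valid_run(run, t, k = k)
  # k at least n reproduces the unbounded result bit for bit
  expect_identical(merge_sort(0:(t$n - 1L), t, k = t$n + 5L),
                   merge_sort(0:(t$n - 1L), t))
})
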