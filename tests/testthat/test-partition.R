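test_that("sample_pivots draws reproducibly and selects evenly spaced ranks", {
  t <- build_text(worked$text)
  expect_identical(sample_pivots(list(merge_sort(0:10, t)), 4, 1, t)$pivots,
                   integer(0))
  runs <- list(merge_sort(0:4, t), merge_sort(5:10, t))
  ps <- sample_pivots(runs, s = 1, seed = 99, text = t)
  # replicate the documented draw: seeded, run by run, without replacement
  set.seed(99)
  idx <- lapply(c(5L, 6L), function(m) sort(sample.int(m, 1)))
  samp <- c(runs[[1]]$positions[idx[[1]]], runs[[2]]$positions[idx[[2]]])
  expected <- merge_sort(samp, t)$positions[2]  # 0-based rank s = 1
  expect_identical(ps$pivots, expected)
  expect_identical(sample_pivots(runs, s = 1, seed = 99, text = t)$pivots,
                   ps$pivots)
})

test_that("sampling factor larger than a run is clamped with a warning", {
  t <- build_text(worked$text)
  runs <- list(merge_sort(0:4, t), merge_sort(5:10, t))
  expect_warning(ps <- sample_pivots(runs, s = 64, seed = 1, text = t),
                 "clamped")
  expect_identical(ps$s, 5L)
  expect_length(ps$pivots, 1L)
})

test_that("pivots are strictly increasing as suffixes", {
  t <- rand_text(600, 4, seed = 21)
  off <- as.integer((as.numeric(0:4) * t$n) %/% 4)
  runs <- lapply(1:4, function(r) merge_sort((off[r]):(off[r + 1] - 1L), t))
  ps <- sample_pivots(runs, s = 8, seed = 5, text = t)
  expect_length(ps$pivots, 3L)
  for (i in 2:length(ps$pivots))
    expect_identical(
      suffix_compare(t, ps$pivots[i - 1L], ps$pivots[i])$relation, "less")
})

test_that("locate_pivot returns upper-bound insertion indices", {
  t <- build_text(worked$text)
  run <- sorted_run(c(10, 0, 1), c(0, 0, 1))
  expect_identical(locate_pivot(run, 8, t), 3L)
  expect_identical(locate_pivot(run, 0, t), 2L)  # after the equal element
  expect_identical(locate_pivot(sorted_run(c(0, 1, 8), c(0, 1, 1)), 10, t), 0L)
})

test_that("locate_pivot equals a naive linear scan, with and without limits", {
  for (seed in 1:12) {
    t <- rand_text(sample(10:400, 1), ab = sample(2:5, 1), seed = seed)
    sa <- brute_force_sa(t)
    keep <- sort(sample(seq_along(sa), ceiling(length(sa) / 2)))
    run <- merge_sort(sa[keep], t)
    v <- sample(0:(t$n - 1L), 1)
    for (pl in c(Inf, 1, 4, 16)) {
      expect_identical(
        locate_pivot(run, v, t,
                     prefix_limit = if (is.finite(pl)) pl else NULL),
        as.integer(naive_locate(run, v, t, prefix_limit = pl)))
    }
  }
})

test_that("collate_partitions builds contiguous partitions that conserve n", {
  t <- build_text(worked$text)
  # p = 1: identity layout
  one <- collate_partitions(list(merge_sort(0:10, t)), integer(0), t)
  expect_identical(one$layout$cumulative, c(0L, 11L))
  expect_identical(one$positions, worked$sa)
  # p = 2 with pivot AT$ (position 8): 4 suffixes are <= AT$
  runs <- list(merge_sort(0:4, t), merge_sort(5:10, t))
  col <- collate_partitions(runs, 8L, t)
  expect_identical(col$layout$cumulative[2], 4L)
  expect_setequal(col$positions[1:4], c(10L, 0L, 1L, 8L))
  expect_setequal(col$positions, 0:10)
  # conservation on seeded random instances
  for (seed in 1:5) {
    tt <- rand_text(sample(20:300, 1), 4, seed = seed)
    off <- as.integer((as.numeric(0:3) * tt$n) %/% 3)
    rr <- lapply(1:3, function(r) merge_sort((off[r]):(off[r + 1] - 1L), tt))
    ps <- sample_pivots(rr, s = 2, seed = seed, text = tt)
    cc <- collate_partitions(rr, ps, tt)
    expect_identical(sum(diff(cc$layout$cumulative)), tt$n)
    expect_setequal(cc$positions, 0:(tt$n - 1L))
  }
})

test_that("merge_partition merges contiguous sorted groups", {
  t <- build_text(worked$text)
  g1 <- sorted_run(c(5, 2), c(0, 1))
  expect_identical(merge_partition(list(g1), t), g1)
  z <- merge_partition(list(g1, sorted_run(c(7, 4), c(0, 1))), t)
  expect_identical(z$positions, c(5L, 2L, 7L, 4L))
  expect_identical(z$lcps, c(0L, 1L, 0L, 1L))
  # empty groups are permitted
  z <- merge_partition(list(g1, sorted_run(integer(0), integer(0))), t)
  expect_identical(z$positions, g1$positions)
})

test_that("collation plus partition merges reconstruct the worked example", {
  t <- build_text(worked$text)
  runs <- list(merge_sort(0:4, t), merge_sort(5:10, t))
  col <- collate_partitions(runs, 8L, t)
  out <- integer(0)
  for (j in 1:2) {
    gb <- col$layout$group_bounds[[j]]
    groups <- lapply(1:2, function(r) {
      span <- if (gb[r + 1L] > gb[r]) (gb[r] + 1L):gb[r + 1L] else integer(0)
      sorted_run(col$positions[span], col$lcps[span])
    })
    out <- c(out, merge_partition(groups, t)$positions)
  }
  expect_identical(out, worked$sa)
})

test_that("modular pipeline composition matches the one-shot construction", {
  tt <- rand_text(800, 4, seed = 31)
  p <- 4L
  idx <- capssa_build(tt, p = p, s = 8, seed = 7)
  off <- as.integer((as.numeric(0:p) * tt$n) %/% p)
  runs <- lapply(1:p, function(r) merge_sort((off[r]):(off[r + 1] - 1L), tt))
  ps <- sample_pivots(runs, s = 8, seed = 7, text = tt)
  col <- collate_partitions(runs, ps, tt)
  expect_identical(col$layout$cumulative, idx$layout$cumulative)
  sa <- integer(0)
  lcp <- integer(0)
  for (j in 1:p) {
    gb <- col$layout$group_bounds[[j]]
    groups <- lapply(1:p, function(r) {
      span <- if (gb[r + 1L] > gb[r]) (gb[r] + 1L):gb[r + 1L] else integer(0)
      sorted_run(col$positions[span], col$lcps[span])
    })
    z <- merge_partition(groups, tt)
    sa <- c(sa, z$positions)
    lcp <- c(lcp, z$lcps)
  }
  lcp <- fix_boundary_lcps(tt, sa, lcp, col$layout)
  expect_identical(sa, idx$sa)
  expect_identical(lcp, idx$lcp)
})
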