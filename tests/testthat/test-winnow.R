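test_that("rolling index equals the brute-force oracle on structured streams", {
  # strictly increasing: sketch is always the first s in-window k-mers
  hs <- hashSequence(seq(0.01, 0.99, length.out = 60))
  for (ws in list(c(5, 1), c(5, 3), c(10, 4))) {
    expect_identical_index(buildMinmerIndex(hs, ws[1], ws[2]),
                           bruteForceIndex(hs, ws[1], ws[2]))
  }
  iv <- minmerIntervals(buildMinmerIndex(hs, 10, 4))
  # increasing staircase: window j keeps its first s k-mers, so the sampled
  # set is 0..(n - w + s - 1)
  expect_identical(sort(unique(iv$pos)), 0:53)

  # strictly decreasing, s = 1: each window's minimizer is its newest k-mer
  hs <- hashSequence(seq(0.99, 0.01, length.out = 20))
  idx <- buildMinmerIndex(hs, 4, 1)
  expect_identical_index(idx, bruteForceIndex(hs, 4, 1))
  iv <- minmerIntervals(idx)
  expect_true(all(iv$end - iv$start == 1L))
  expect_identical(sort(unique(iv$pos)), 3:19)
  expect_identical(nrow(iv), 17L)  # one length-1 interval per window

  # s = w: every position is in every subsuming sketch; interval density 1
  hs <- hashSequence(makeStream(200, "continuous", 5))
  idx <- buildMinmerIndex(hs, 8, 8)
  expect_identical_index(idx, bruteForceIndex(hs, 8, 8))
  expect_identical(nrow(minmerIntervals(idx)), 200L)
  expect_identical(sort(unique(minmerIntervals(idx)$pos)), 0:199)
})

test_that("rolling index equals the oracle across random and duplicate-heavy cases", {
  set.seed(11)
  for (rep in 1:80) {
    n <- sample(25:250, 1)
    w <- sample(2:20, 1)
    s <- sample.int(w, 1)
    mode <- c("continuous", "coarse", "fine", "constant")[1 + rep %% 4]
    hs <- hashSequence(makeStream(n, mode, 1000 + rep))
    expect_identical_index(buildMinmerIndex(hs, w, s),
                           bruteForceIndex(hs, w, s))
  }
  # n < w edge: one window of effective length n
  hs <- hashSequence(makeStream(7, "continuous", 1))
  a <- buildMinmerIndex(hs, 50, 3)
  expect_identical_index(a, bruteForceIndex(hs, 50, 3))
  expect_identical(windowCount(a), 1L)
  expect_identical(nrow(minmerIntervals(a)), 3L)
  expect_true(all(minmerIntervals(a)$end == 1L))
})

test_that("windowSketch recovers the bottom-s of every window by stabbing", {
  hs <- hashSequence(makeStream(1000, "continuous", 21))
  idx <- buildMinmerIndex(hs, 50, 5)
  h <- hashValues(hs)
  for (j in seq(0, windowCount(idx) - 1)) {
    expect_identical(hashValues(windowSketch(idx, j)),
                     directBottomSketch(h, j, 50, 5))
  }
  expect_error(windowSketch(idx, -1), "out of range")
  expect_error(windowSketch(idx, windowCount(idx)), "out of range")
})

test_that("exactly s intervals stab each window with enough distinct k-mers", {
  hs <- hashSequence(makeStream(800, "continuous", 8))
  idx <- buildMinmerIndex(hs, 40, 6)
  iv <- minmerIntervals(idx)
  for (j in seq(0, windowCount(idx) - 1, by = 7)) {
    stabbed <- iv$hash[iv$start <= j & iv$end > j]
    expect_identical(length(unique(stabbed)), 6L)
  }
})

test_that("a larger window's sketch is covered by overlapping minmer intervals", {
  w <- 50; wPrime <- 80; s <- 5
  hs <- hashSequence(makeStream(600, "continuous", 31))
  idx <- buildMinmerIndex(hs, w, s)
  iv <- minmerIntervals(idx)
  h <- hashValues(hs)
  for (j in seq(0, 600 - wPrime, by = 13)) {
    bigSketch <- directBottomSketch(h, j, wPrime, s)
    covering <- unique(iv$hash[iv$start <= (j + wPrime - w) & iv$end > j])
    expect_true(all(bigSketch %in% covering))
  }
})

test_that("minmer positions generalize minimizers and match the index", {
  hs <- hashSequence(makeStream(1500, "continuous", 77))
  # s = 1 reduces to the classic minimizer scheme
  expect_identical(minmerPositions(hs, 25, 1), minimizerPositions(hs, 25))
  # positions are exactly the pos fields of the interval index
  idx <- buildMinmerIndex(hs, 10, 3)
  expect_identical(minmerPositions(hs, 10, 3), sort(unique(minmerIntervals(idx)$pos)))
  # minimizers are a strict subset of minmers at s > 1
  mm <- minmerPositions(hs, 10, 3)
  mz <- minimizerPositions(hs, 10)
  expect_true(all(mz %in% mm))
  expect_gt(length(mm), length(mz))
})

test_that("the scheme is non-forward: positions recur in disjoint intervals", {
  hs <- hashSequence(makeStream(2000, "continuous", 13))
  iv <- minmerIntervals(buildMinmerIndex(hs, 10, 2))
  dup <- iv$pos[duplicated(iv$pos)]
  expect_gt(length(dup), 0L)
  p <- dup[1]
  rows <- iv[iv$pos == p, ]
  rows <- rows[order(rows$start), ]
  # maximal membership runs: consecutive intervals of one position are
  # separated by windows where the k-mer dropped out of the sketch
  expect_true(all(rows$end[-nrow(rows)] < rows$start[-1]))
})

test_that("window guarantee holds for minmers and window-matched minimizers", {
  w <- 60; s <- 4
  hs <- hashSequence(makeStream(2000, "continuous", 55))
  pos <- minmerPositions(hs, w, s)
  expect_true(checkWindowGuarantee(pos, hs, w, s)$ok)
  # a floor(w/s)-minimizer scheme also satisfies the (w, s) guarantee
  mz <- minimizerPositions(hs, w %/% s)
  expect_true(checkWindowGuarantee(mz, hs, w, s)$ok)
  # deleting a sampled position breaks it, reporting the right window:
  # with increasing hashes the minimizer of window j is position j, so the
  # last window's only sampled position is n - w
  hsInc <- hashSequence(seq(0.01, 0.99, length.out = 50))
  mzi <- minimizerPositions(hsInc, 4)
  expect_identical(mzi, 0:46)
  bad <- checkWindowGuarantee(setdiff(mzi, 46L), hsInc, 4, 1)
  expect_false(bad$ok)
  expect_identical(bad$window, 46L)
})

test_that("density is monotone in s and heap pruning is amortized O(1)", {
  hs <- randomHashStream(50000, seed = 3)
  w <- 20L
  dens <- vapply(c(1L, 2L, 5L, 10L, 20L), function(s)
    empiricalDensity(minmerPositions(hs, w, s), 50000), numeric(1))
  expect_true(all(diff(dens) > 0))
  expect_equal(dens[5], 1)  # s = w samples everything
  idx <- buildMinmerIndex(hs, 100, 10)
  expect_lte(idx@heapPrunes, 50000 / 100)
  # density factor of a w-minimizer scheme is ~2
  expect_equal(empiricalDensityFactor(minimizerPositions(hs, 100), 50000, 100),
               2, tolerance = 0.05)
  expect_equal(empiricalDensity(0:(50000 - 1), 50000), 1)
})

test_that("index serialization round-trips exactly", {
  dna <- randomDna(4000, seed = 9)
  idx <- buildMinmerIndex(kmerHashSequence(dna, k = 13, seed = 5), 100, 8)
  path <- tempfile(fileext = ".tsv")
  writeMinmerIndex(idx, path)
  back <- readMinmerIndex(path)
  for (sl in slotNames(idx)) {
    expect_identical(slot(back, sl), slot(idx, sl))
  }
  unlink(path)
})
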