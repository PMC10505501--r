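test_that("interval density closed form matches its special cases", {
  expect_equal(intervalDensity(3, 1), 0.5)
  expect_equal(intervalDensity(5, 3), 0.8)
  w <- 1:1000
  expect_equal(intervalDensity(w, 1), 2 / (w + 1), tolerance = 1e-14)
  expect_equal(intervalDensity(64, 64), 1)
  expect_error(intervalDensity(5, 6), "1 <= s <= w")
})

test_that("minmer density closed form agrees with the rank-walk DP", {
  for (ws in list(c(6, 2), c(10, 2), c(12, 5), c(20, 3), c(35, 8))) {
    expect_equal(minmerDensity(ws[1], ws[2]),
                 minmerDensity(ws[1], ws[2], method = "rank_walk"),
                 tolerance = 1e-10)
  }
  # s = 1 reduces to the minimizer density 2/(w+1)
  expect_equal(minmerDensity(10, 1), 2 / 11, tolerance = 1e-10)
  expect_equal(minmerDensity(30, 1), 2 / 31, tolerance = 1e-10)
  expect_equal(minmerDensity(17, 17), 1)
  # minmer count is bounded by interval count
  for (ws in list(c(10, 2), c(20, 3), c(50, 5), c(30, 1))) {
    expect_lte(minmerDensity(ws[1], ws[2]), intervalDensity(ws[1], ws[2]))
  }
})

test_that("spread pmf is a normalized distribution with the df=2 limit", {
  u <- spreadPmf(100, 2)
  expect_equal(u$p, rep(1 / 100, 100))
  for (df in c(3, 5, 10)) {
    p <- spreadPmf(50, df)$p
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # non-integer df interpolates smoothly between integer neighbours
  p25 <- spreadPmf(40, 2.5)$p
  expect_true(all(p25 >= pmin(spreadPmf(40, 2)$p, spreadPmf(40, 3)$p) - 1e-9))
})

test_that("spread approximation matches empirical minmer gaps", {
  w <- 100L; s <- 10L; n <- 3e5
  hs <- randomHashStream(n, seed = 17)
  pos <- minmerPositions(hs, w, s)
  df <- empiricalDensityFactor(pos, n, w)
  gaps <- diff(pos)
  expect_lte(max(gaps), w)  # window guarantee caps the spread
  emp <- tabulate(gaps, w) / length(gaps)
  tv <- 0.5 * sum(abs(emp - spreadPmf(w, df)$p))
  expect_lt(tv, 0.05)
})

test_that("empirical index size matches n * interval density", {
  n <- 2e5
  hs <- randomHashStream(n, seed = 23)
  for (ws in list(c(5, 3), c(50, 10))) {
    idx <- buildMinmerIndex(hs, ws[1], ws[2])
    iv <- minmerIntervals(idx)
    se <- blockSE(iv$start, n)
    expect_lt(abs(nrow(iv) / n - intervalDensity(ws[1], ws[2])), 3 * se)
  }
})

test_that("density comparison reproduces the minimizer-vs-minmer gap", {
  tab <- densityComparisonTable(200L, sGrid = c(1L, 5L, 20L, 200L),
                                n = 2e5, seed = 29)
  # s = 1 and s = w rows: equal densities (same scheme)
  expect_equal(tab$minmerDensity[1], tab$minimizerDensity[1])
  expect_equal(tab$minmerDensity[4], tab$minimizerDensity[4])
  # intermediate s: minimizer density strictly larger
  expect_true(all(tab$excessPct[2:3] > 0))
})
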