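test_that("endpoint sweep finds maximal qualifying regions", {
  reg <- sweepCandidateRegions(c(2, 5, 6), c(7, 9, 8), minCount = 3)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$start, 6)
  expect_identical(reg$end, 7)
  expect_identical(reg$maxOverlap, 3L)
  # lower threshold: one merged region over the union
  reg2 <- sweepCandidateRegions(c(2, 5, 6), c(7, 9, 8), minCount = 1)
  expect_identical(reg2$start, 2)
  expect_identical(reg2$end, 9)
  expect_identical(reg2$maxOverlap, 3L)
  expect_identical(nrow(sweepCandidateRegions(numeric(0), numeric(0), 1)), 0L)
})

test_that("stage 1 localizes an exact query with full sketch overlap", {
  hs <- randomHashStream(5000, seed = 41)
  w <- 200L; s <- 20L
  idx <- buildMinmerIndex(hs, w, s)
  j0 <- 1234L
  qsk <- bottomSketch(hashValues(hs)[(j0 + 1):(j0 + w)], s)
  reg <- stage1Candidates(qsk, idx, mapParams(aniThreshold = 0.85))
  hit <- reg[reg$start <= j0 & reg$end > j0, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$maxOverlap, s)
})

test_that("random query against an unrelated reference yields no candidates", {
  ref <- randomDna(50000, seed = 51)
  idx <- buildMinmerIndex(kmerHashSequence(ref, k = 19), 2000, 100)
  hits <- 0L
  for (i in 1:10) {
    qry <- randomDna(2100, seed = 600 + i)
    qsk <- bottomSketch(kmerHashSequence(qry, k = 19), 100)
    hits <- hits + nrow(stage1Candidates(qsk, idx, mapParams(aniThreshold = 0.85)))
  }
  expect_identical(hits, 0L)
})

test_that("the numerator pmf is hypergeometric with the right edge cases", {
  p1 <- minhashNumeratorPmf(10, 10)
  expect_equal(p1$p[p1$y == 10], 1)
  p0 <- minhashNumeratorPmf(10, 0)
  expect_equal(p0$p[p0$y == 0], 1)
  pm <- minhashNumeratorPmf(100, 50)
  expect_equal(sum(pm$p), 1)
  expect_equal(pm$p, dhyper(0:50, 50, 100, 100))
})

test_that("the delta-ANI prefilter drops hopeless regions and keeps the rest", {
  s <- 100L; k <- 19L
  regions <- data.frame(refName = "r", start = c(0, 500, 900),
                        end = c(100, 600, 1000), maxOverlap = c(100L, 50L, 2L))
  # huge deltaAni: kappa = 0, nothing dropped
  loose <- deltaAniPrefilter(regions, mapParams(deltaAni = 1), s, k)
  expect_identical(nrow(loose), 3L)
  # tight deltaAni with a perfect best: the ci = s region survives, the
  # half-overlap and tiny regions cannot reach within deltaAni of ANI 1
  tight <- deltaAniPrefilter(regions, mapParams(deltaAni = 0.001), s, k)
  expect_identical(tight$maxOverlap, 100L)
  # a region with ci < kappa has Pr(Y >= kappa) = 0: always dropped
  kap <- ceiling(s * aniToJaccard(jaccardToAni(50 / s, k) - 0.001, k))
  expect_gt(kap, 2)  # the ci = 2 region is below kappa for this setup
})

test_that("stage 2 equals the direct per-window minhash estimator", {
  for (rep in 1:5) {
    hs <- randomHashStream(1200, seed = 70 + rep)
    idx <- buildMinmerIndex(hs, 150, 15)
    h <- hashValues(hs)
    # query shares a corrupted slice of the reference
    q <- h[301:500]
    set.seed(rep); corrupt <- sample(200, 60)
    q[corrupt] <- runif(60)
    qsk <- bottomSketch(q, 15)
    st2 <- stage2RollingMinhash(qsk, idx, c(0, windowCount(idx)))
    for (j in seq(0, windowCount(idx) - 1, by = 11)) {
      oracle <- directWindowMinhash(hashValues(qsk), h, j, 150, 15)
      expect_identical(st2$numerator[j + 1], oracle$numerator)
      expect_identical(st2$denominator[j + 1], oracle$denominator)
    }
  }
})

test_that("exact and reverse-complement copies map to the true locus", {
  ref <- randomDna(30000, seed = 81)
  idx <- buildMinmerIndex(kmerHashSequence(ref, k = 15), 1000, 40)
  q <- substr(ref, 10001, 12100)
  mp <- mapQuery(q, idx, mapParams(aniThreshold = 0.9), queryName = "q1")
  expect_gt(nrow(mp), 0L)
  expect_true(all(mp$strand == "+"))
  expect_true(all(mp$jaccard == 1))
  expect_true(all(mp$ani == 1))
  expect_true(all(mp$numerator == mp$denominator))
  # reported locus covers the true one
  expect_true(any(abs(mp$tstart - 10000) <= 1000))
  expect_identical(mp$query[1], "q1")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  mrc <- mapQuery(rc, idx, mapParams(aniThreshold = 0.9))
  expect_gt(nrow(mrc), 0L)
  expect_true(all(mrc$strand == "-"))
  expect_true(any(mrc$jaccard == 1))

  expect_warning(res <- mapQuery("ACGT", idx), "shorter than k")
  expect_identical(nrow(res), 0L)
})

test_that("mapping localizes diverged queries near the true position", {
  ref <- randomDna(100000, seed = 91)
  w <- 500L; s <- 30L; k <- 16L
  idx <- buildMinmerIndex(kmerHashSequence(ref, k = k), w, s)
  set.seed(92)
  offs <- sample.int(100000 - 600, 20)
  hit <- 0L
  for (i in seq_along(offs)) {
    sl <- substr(ref, offs[i], offs[i] + 514)
    mut <- mutateSequence(sl, 0.03, seed = 700 + i, k = k)
    mp <- mapQuery(mut$sequence, idx, mapParams(aniThreshold = 0.85))
    if (nrow(mp) && abs(mp$tstart[1] - (offs[i] - 1)) <= w) hit <- hit + 1L
  }
  expect_gte(hit, 19L)
})

test_that("PAF output is well-formed", {
  ref <- randomDna(20000, seed = 93)
  idx <- buildMinmerIndex(kmerHashSequence(ref, k = 15), 800, 30)
  mp <- mapQuery(substr(ref, 3001, 4700), idx, queryName = "readA")
  path <- tempfile(fileext = ".paf")
  writePaf(mp, path)
  fields <- strsplit(readLines(path), "\t")
  expect_true(all(lengths(fields) == 15L))
  expect_identical(fields[[1]][1], "readA")
  expect_identical(fields[[1]][5], "+")
  unlink(path)
})

test_that("winnowed-minhash baseline is exact for identical sequences", {
  hs <- kmerHashSequence(randomDna(5000, seed = 95), k = 15)
  est <- winnowedMinhashJaccard(hs, hs, w = 50)
  expect_equal(est$jaccard, 1)
})
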