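test_that("bottomSketch returns the s smallest distinct values", {
  expect_identical(hashValues(bottomSketch(c(0.5, 0.1, 0.9, 0.3), 2)),
                   c(0.1, 0.3))
  expect_identical(hashValues(bottomSketch(c(0.1, 0.1, 0.2), 3)),
                   c(0.1, 0.2))
  expect_identical(hashValues(bottomSketch(c(0.7, 0.2), 10)), c(0.2, 0.7))
  expect_length(hashValues(bottomSketch(numeric(0), 5)), 0L)
  expect_length(hashValues(bottomSketch(c(NA, 0.3), 5)), 1L)
})

test_that("minhashJaccard matches the set Jaccard when s covers the union", {
  set.seed(1)
  vals <- runif(15)  # 15 distinct "k-mer hashes"
  A <- vals[1:10]; B <- vals[6:15]
  est <- minhashJaccard(bottomSketch(A, 15), bottomSketch(B, 15))
  expect_identical(est$numerator, 5L)
  expect_identical(est$denominator, 15L)
  expect_equal(est$jaccard, 1 / 3)

  idn <- minhashJaccard(bottomSketch(A, 5), bottomSketch(A, 5))
  expect_equal(idn$jaccard, 1)
  dis <- minhashJaccard(bottomSketch(vals[1:7], 5), bottomSketch(vals[8:15], 5))
  expect_equal(dis$jaccard, 0)

  expect_error(minhashJaccard(bottomSketch(numeric(0), 3),
                              bottomSketch(numeric(0), 3)), "empty")
  expect_error(minhashJaccard(bottomSketch(A, 3), bottomSketch(B, 4)),
               "different s")
})

test_that("minhash estimator is unbiased over random hash orders", {
  # fixed sets sharing 60 of 140 elements: J = 60/220... compute exactly
  nA <- 150; shared <- 60
  J <- shared / (2 * nA - shared)
  s <- 40
  reps <- 400
  est <- vapply(seq_len(reps), function(i) {
    set.seed(i)
    vals <- runif(2 * nA - shared)
    A <- vals[seq_len(nA)]
    B <- c(vals[seq_len(shared)], vals[(nA + 1):(2 * nA - shared)])
    minhashJaccard(bottomSketch(A, s), bottomSketch(B, s))$jaccard
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - J), 3 * se)
})

test_that("estimator standard deviation scales as 1/sqrt(s)", {
  nA <- 2000; shared <- 1000
  reps <- 150
  sdAt <- function(s) {
    sd(vapply(seq_len(reps), function(i) {
      set.seed(1000 + i)
      vals <- runif(2 * nA - shared)
      A <- vals[seq_len(nA)]
      B <- c(vals[seq_len(shared)], vals[(nA + 1):(2 * nA - shared)])
      minhashJaccard(bottomSketch(A, s), bottomSketch(B, s))$jaccard
    }, numeric(1)))
  }
  ratio <- sdAt(100L) / sdAt(400L)
  expect_gt(ratio, 1.5)   # ideal ratio 2
  expect_lt(ratio, 2.7)
})

test_that("Jaccard-ANI conversion follows the binomial model and inverts", {
  expect_equal(jaccardToAni(1, 19), 1)
  expect_equal(jaccardToAni(0, 19), 0)  # sentinel
  x <- c(1e-6, 0.01, 0.3, 0.7, 1)
  expect_equal(aniToJaccard(jaccardToAni(x, 19), 19), x, tolerance = 1e-12)
  # known value: divergence d gives j = t/(2-t), t = (1-d)^k
  t <- 0.99^21
  expect_equal(jaccardToAni(t / (2 - t), 21), 0.99, tolerance = 1e-12)
})
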