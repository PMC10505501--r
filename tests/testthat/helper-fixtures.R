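# shared helpers: small independent oracles and stream generators

# bottom-s distinct hashes of window j, by direct sorting (definitional oracle)
directBottomSketch <- function(h, j, w, s) {
  win <- h[(j + 1):min(j + w, length(h))]
  win <- win[!is.na(win)]
  u <- sort(unique(win))
  u[seq_len(min(s, length(u)))]
}

# direct minhash of a query sketch vs window j (oracle for stage 2)
directWindowMinhash <- function(qs, h, j, w, s) {
  b <- directBottomSketch(h, j, w, s)
  u <- sort(unique(c(qs, b)))
  den <- min(as.integer(s), length(u))
  u <- u[seq_len(den)]
  list(numerator = as.integer(sum(u %in% qs & u %in% b)), denominator = den)
}

# hash streams of varying duplicate structure: "continuous" (no duplicates),
# "coarse"/"fine" (heavy/moderate duplication), "constant" (all equal)
makeStream <- function(n, mode, seed) {
  set.seed(seed)
  switch(mode,
         continuous = runif(n),
         coarse = round(runif(n) * 4) / 4,
         fine = round(runif(n) * 32) / 32,
         constant = rep(0.5, n))
}

# standard error of a per-position rate from 100 position blocks, to respect
# the short-range dependence of winnowing indicators
blockSE <- function(positions, n, nBlocks = 100) {
  bs <- ceiling(n / nBlocks)
  counts <- tabulate(positions %/% bs + 1L, nBlocks)
  stats::sd(counts / bs) / sqrt(nBlocks)
}

expect_identical_index <- function(a, b) {
  expect_identical(minmerIntervals(a), minmerIntervals(b))
}
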