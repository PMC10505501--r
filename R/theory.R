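#' Closed-form density of minmer intervals
#'
#' The expected number of minmer intervals per k-mer position of a long
#' random sequence, equivalently the probability that the bottom-s sketch
#' changes between consecutive windows:
#' \deqn{d^*(w,s) = 1 - \frac{(w-s+1)(w-s)}{w(w+1)}.}
#' At s = 1 this equals the classic minimizer density 2 / (w + 1); at s = w
#' every position starts an interval and the density is 1.  The expected
#' index size is n * d*(w, s).
#'
#' @param w window length in k-mers.
#' @param s sketch size, \code{1 <= s <= w} (vectorized over both).
#' @return The interval density in (0, 1].
#' @examples
#' intervalDensity(3, 1)        # = 2 / (w + 1) = 0.5
#' intervalDensity(5, 3)        # = 0.8
#' @export
intervalDensity <- function(w, s) {
  if (any(s < 1 | s > w)) stop("need 1 <= s <= w")
  1 - (w - s + 1) * (w - s) / (w * (w + 1))
}

# Pr(Rw = rw | r1): rank in the last subsuming window given rank r1 in the
# first; rw - 1 ~ BetaBinomial(w - 1 trials, shape r1, w - r1 + 1)
.rankTransition <- function(w, r1) {
  rw <- seq_len(w)
  kk <- rw - 1
  nn <- w - 1
  exp(lchoose(nn, kk) + lbeta(r1 + kk, (w - r1 + 1) + nn - kk) -
        lbeta(r1, w - r1 + 1))
}

# Pr(k-mer is ever a minmer | r1, rw), both ranks > s: a ballot-style
# touching probability for the rank bridge, mixed over the hypergeometric
# count U of smaller-exit events in the last w - rw slides
.everMinmerGivenRanks <- function(w, s, r1, rw) {
  delta <- min(r1 - 1, w - rw)
  u <- 0:delta
  pu <- stats::dhyper(u, r1 - 1, (w - 1) - (r1 - 1), w - rw)
  nn <- 2 * u + rw - r1
  k1 <- u + rw - s
  ok <- nn >= 0 & k1 >= 0 & k1 <= nn
  ratio <- numeric(length(u))
  ratio[ok] <- exp(lchoose(nn[ok], k1[ok]) - lchoose(nn[ok], u[ok]))
  sum(pu * ratio)
}

#' Expected density of the (w, s)-minmer scheme
#'
#' Fraction of k-mer positions of a long random sequence sampled by the
#' minmer scheme.  The closed form follows the rank of a k-mer across its w
#' subsuming windows: with rank r1 in the first window, the rank in the last
#' window is beta-binomially distributed, and the probability of ever
#' entering a bottom-s sketch is a ballot-type touching probability mixed
#' over a hypergeometric.  \code{method = "rank_walk"} evaluates the same
#' quantity by exact dynamic programming over the rank walk and serves as an
#' independent cross-check of the closed form (both are exact; they agree to
#' floating-point accuracy).
#'
#' At s = 1 the value matches the minimizer density 2 / (w + 1); at s = w it
#' is 1.  Evaluation is O(w^3): intended for w up to a few hundred.
#'
#' @param w window length in k-mers.
#' @param s sketch size.
#' @param method \code{"closed_form"} (default) or \code{"rank_walk"}.
#' @return The minmer density in (0, 1].
#' @examples
#' minmerDensity(10, 2)
#' abs(minmerDensity(20, 1) - 2 / 21) < 1e-12
#' @export
minmerDensity <- function(w, s, method = c("closed_form", "rank_walk")) {
  method <- match.arg(method)
  w <- as.integer(w); s <- as.integer(s)
  if (is.na(w) || is.na(s) || s < 1L || s > w) stop("need 1 <= s <= w")
  if (s == w) return(1)
  if (method == "rank_walk") return(cpp_minmer_density_dp(w, s))
  total <- s  # r1 <= s: always a minmer
  for (r1 in (s + 1L):w) {
    prw <- .rankTransition(w, r1)
    total <- total + sum(prw[seq_len(s)])  # rw <= s: always a minmer
    for (rw in (s + 1L):w) {
      total <- total + prw[rw] * .everMinmerGivenRanks(w, s, r1, rw)
    }
  }
  total / w
}

#' Approximate distribution of the spread between adjacent minmers
#'
#' For a (w, s)-minmer scheme with measured density factor df, the distance
#' G between consecutive sampled positions is approximately distributed as
#' \deqn{\Pr(G = d) \approx \binom{w-d}{df-2} / \binom{w}{df-1},}
#' with binomial coefficients generalized through the Gamma function for
#' non-integer df.  The returned mass function is normalized over the valid
#' support 1..w (the window guarantee caps gaps at w).  At df = 2 the
#' distribution is uniform on 1..w.
#'
#' @param w window length in k-mers.
#' @param df density factor (>= 2 for a meaningful approximation).
#' @return A data.frame with columns \code{d} and \code{p}.
#' @examples
#' head(spreadPmf(100, 2.5))
#' @export
spreadPmf <- function(w, df) {
  stopifnot(w >= 1, df >= 2)
  gchoose <- function(n, k) {
    out <- numeric(length(n))
    ok <- (n - k > -1) & (k > -1) & (n > -1)
    out[ok] <- exp(lgamma(n[ok] + 1) - lgamma(k[ok] + 1) -
                     lgamma(n[ok] - k[ok] + 1))
    out
  }
  d <- seq_len(w)
  p <- gchoose(w - d, rep(df - 2, w)) / gchoose(w, df - 1)
  tot <- sum(p)
  if (tot <= 0) stop("degenerate spread distribution for df=", df)
  data.frame(d = d, p = p / tot)
}

#' Density comparison: (w, s)-minmers versus window-matched minimizers
#'
#' A \code{floor(w/s)}-minimizer scheme satisfies the same (w, s)-window
#' guarantee as the (w, s)-minmer scheme.  This table estimates both
#' densities empirically on an i.i.d. uniform hash stream (plus the
#' closed-form minmer-interval density and minimizer density) for a grid of
#' sketch sizes, and reports the percentage excess of the minimizer scheme's
#' density.
#'
#' @param w minmer window length (default 1000).
#' @param sGrid sketch sizes to tabulate.
#' @param n length of the hash stream.
#' @param seed RNG seed for the stream.
#' @return A data.frame with columns \code{s}, \code{minmerDensity},
#'   \code{intervalDensity}, \code{minimizerW}, \code{minimizerDensity},
#'   \code{excessPct}.
#' @export
densityComparisonTable <- function(w = 1000L,
                                   sGrid = c(2L, 5L, 10L, 20L, 30L, 40L, 50L,
                                             64L, 80L, 100L, 150L, 200L,
                                             333L, 500L),
                                   n = 1e6, seed = 1L) {
  hs <- randomHashStream(n, seed = seed)
  rows <- lapply(sGrid, function(s) {
    wPrime <- as.integer(floor(w / s))
    dMinmer <- empiricalDensity(minmerPositions(hs, w, s), n)
    dMinimizer <- empiricalDensity(minimizerPositions(hs, wPrime), n)
    data.frame(s = s,
               minmerDensity = dMinmer,
               intervalDensity = intervalDensity(w, s),
               minimizerW = wPrime,
               minimizerDensity = dMinimizer,
               excessPct = 100 * (dMinimizer / dMinmer - 1))
  })
  do.call(rbind, rows)
}
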