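#' @rdname bottomSketch
#' @export
setMethod("bottomSketch", "numeric", function(x, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("'s' must be a positive integer")
  h <- sort(unique(x[!is.na(x)]))
  h <- h[seq_len(min(s, length(h)))]
  new("BottomSketch", hashes = h, s = s, orientations = logical(0))
})

#' @rdname bottomSketch
#' @export
setMethod("bottomSketch", "HashSequence", function(x, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("'s' must be a positive integer")
  keep <- !is.na(x@hashes)
  h <- x@hashes[keep]
  o <- if (length(x@orientations)) x@orientations[keep] else
    rep(NA, sum(keep))
  # leftmost occurrence of each distinct hash carries the orientation bit
  first <- !duplicated(h)
  h <- h[first]; o <- o[first]
  ord <- order(h)
  take <- ord[seq_len(min(s, length(h)))]
  new("BottomSketch", hashes = h[take], s = s, orientations = o[take])
})

#' Minhash estimator of the Jaccard similarity
#'
#' Estimates J(A, B) from two bottom-s sketches as
#' numerator / denominator, where the denominator is the size of the bottom-s
#' sketch of the union (at most s, fewer for tiny inputs) and the numerator
#' counts members of the union sketch present in both input sketches.  The
#' estimator is unbiased for the true set Jaccard.
#'
#' @param a,b \linkS4class{BottomSketch} objects built with the same s and
#'   hash seed.
#' @return A list with elements \code{jaccard}, \code{numerator},
#'   \code{denominator}.
#' @examples
#' a <- bottomSketch(c(0.1, 0.2, 0.3), s = 3)
#' b <- bottomSketch(c(0.1, 0.2, 0.9), s = 3)
#' minhashJaccard(a, b)
#' @export
minhashJaccard <- function(a, b) {
  stopifnot(is(a, "BottomSketch"), is(b, "BottomSketch"))
  if (a@s != b@s)
    stop("sketches built with different s (", a@s, " vs ", b@s, ")")
  if (length(a@hashes) == 0L && length(b@hashes) == 0L)
    stop("both sketches are empty: Jaccard undefined")
  u <- sort(unique(c(a@hashes, b@hashes)))
  den <- min(a@s, length(u))
  u <- u[seq_len(den)]
  num <- sum(u %in% a@hashes & u %in% b@hashes)
  list(jaccard = num / den, numerator = as.integer(num),
       denominator = as.integer(den))
}

#' Convert between Jaccard similarity and ANI
#'
#' Uses the binomial k-mer mutation model: under a per-base substitution rate
#' d, a fraction t = (1 - d)^k of k-mers is expected to survive, giving a
#' Jaccard of j = t / (2 - t) between two equal-sized k-mer sets.  Inverting,
#' \code{jaccardToAni} computes ANI = (2j / (1 + j))^(1/k) and
#' \code{aniToJaccard} is its exact inverse on (0, 1].  A Jaccard of 0 maps
#' to the sentinel ANI 0 ("no detectable similarity").
#'
#' @param jaccard estimated Jaccard in [0, 1].
#' @param ani average nucleotide identity in [0, 1].
#' @param k k-mer length used for the sketches.
#' @return \code{jaccardToAni}: ANI in [0, 1]; \code{aniToJaccard}: Jaccard
#'   in [0, 1].
#' @examples
#' jaccardToAni(1, 19)                     # identical sequences
#' aniToJaccard(jaccardToAni(0.3, 19), 19) # round trip
#' @export
jaccardToAni <- function(jaccard, k) {
  stopifnot(all(jaccard >= 0 & jaccard <= 1, na.rm = TRUE), k >= 1)
  t <- 2 * jaccard / (1 + jaccard)
  ani <- ifelse(jaccard <= 0, 0, t^(1 / k))
  pmin(pmax(ani, 0), 1)
}

#' @rdname jaccardToAni
#' @export
aniToJaccard <- function(ani, k) {
  stopifnot(all(ani >= 0 & ani <= 1, na.rm = TRUE), k >= 1)
  t <- ani^k
  t / (2 - t)
}
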