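.newMinmerIndex <- function(res, hseq, w, s, refLength) {
  m <- length(res$hash)
  new("MinmerIndex",
      hash = res$hash, pos = res$pos, start = res$start, end = res$end,
      orient = res$orient,
      hashOrder = if (m) order(res$hash, res$start) else integer(0),
      w = w, s = s, k = hseq@k, seed = hseq@seed, canonical = hseq@canonical,
      n = length(hseq@hashes),
      nWindows = max(1L, length(hseq@hashes) - w + 1L),
      refName = hseq@sourceName,
      refLength = as.integer(refLength),
      heapPrunes = as.integer(res$heapPrunes))
}

.checkWinnowArgs <- function(hseq, w, s) {
  stopifnot(is(hseq, "HashSequence"))
  w <- as.integer(w); s <- as.integer(s)
  if (is.na(w) || w < 1L) stop("'w' must be a positive integer")
  if (is.na(s) || s < 1L || s > w) stop("need 1 <= s <= w")
  if (length(hseq@hashes) == 0L) stop("empty HashSequence")
  list(w = w, s = s)
}

#' Build the rolling minmer-interval index
#'
#' Slides a window of \code{w} k-mers over the hash sequence while
#' maintaining its bottom-\code{s} sketch in a sorted map \code{M} and the
#' remaining in-window hashes in a min-heap \code{H} with lazy deletion (the
#' heap is pruned whenever it exceeds 2w entries).  Whenever a hash leaves
#' the sketch, the minmer intervals of its active positions are closed and
#' appended to the index; open intervals are closed past the last window.
#' Duplicate k-mers are handled by keeping all active positions of a sketch
#' hash, each with its own interval.  The result lists intervals sorted by
#' start, with a hash-ordered lookup permutation.
#'
#' @param hseq a \linkS4class{HashSequence}.
#' @param w window length in k-mers.  Sequences shorter than \code{w} are
#'   treated as a single window of their full length.
#' @param s sketch size, \code{1 <= s <= w}.  Windows with fewer than s
#'   distinct k-mers keep all of them.
#' @return A \linkS4class{MinmerIndex}.
#' @seealso \code{\link{bruteForceIndex}} for the quadratic reference
#'   implementation, \code{\link{windowSketch}} for querying.
#' @examples
#' hs <- hashSequence(runif(100))
#' idx <- buildMinmerIndex(hs, w = 10, s = 3)
#' idx
#' @export
buildMinmerIndex <- function(hseq, w, s) {
  a <- .checkWinnowArgs(hseq, w, s)
  res <- cpp_build_minmer_index(hseq@hashes, a$w, a$s,
                                if (length(hseq@orientations))
                                  hseq@orientations else NULL)
  refLength <- length(hseq@hashes) + if (hseq@k > 1L) hseq@k - 1L else 0L
  .newMinmerIndex(res, hseq, a$w, a$s, refLength)
}

#' Brute-force minmer-interval index (test oracle)
#'
#' Computes the bottom-s distinct hashes of every window by full sorting and
#' derives minmer intervals as maximal membership runs per (hash, position).
#' Quadratic in the sequence length; intended as the ground-truth oracle for
#' \code{\link{buildMinmerIndex}} on small inputs.
#'
#' @inheritParams buildMinmerIndex
#' @return A \linkS4class{MinmerIndex} identical to the rolling construction.
#' @export
bruteForceIndex <- function(hseq, w, s) {
  a <- .checkWinnowArgs(hseq, w, s)
  res <- cpp_brute_force_index(hseq@hashes, a$w, a$s,
                               if (length(hseq@orientations))
                                 hseq@orientations else NULL)
  refLength <- length(hseq@hashes) + if (hseq@k > 1L) hseq@k - 1L else 0L
  .newMinmerIndex(res, hseq, a$w, a$s, refLength)
}

#' Retrieve the bottom-s sketch of a window by interval stabbing
#'
#' The s smallest distinct hashes of window \code{Wj} are exactly the hashes
#' whose minmer intervals contain \code{j}; no sorting of the raw window is
#' performed.
#'
#' @param index a \linkS4class{MinmerIndex}.
#' @param j window start (0-based, \code{0 <= j < windowCount(index)}).
#' @return A \linkS4class{BottomSketch}.
#' @export
windowSketch <- function(index, j) {
  stopifnot(is(index, "MinmerIndex"))
  if (length(j) != 1L || is.na(j) || j < 0 || j >= index@nWindows)
    stop("window start j out of range [0, ", index@nWindows - 1L, "]")
  sel <- which(index@start <= j & index@end > j)
  h <- index@hash[sel]
  o <- index@orient[sel]
  first <- !duplicated(h)
  h <- h[first]; o <- o[first]
  ord <- order(h)
  take <- ord[seq_len(min(index@s, length(h)))]
  new("BottomSketch", hashes = h[take], s = index@s, orientations = o[take])
}

#' Sampled positions of winnowing schemes
#'
#' \code{minmerPositions} returns the set of k-mer positions sampled by the
#' (w, s)-minmer scheme: every position whose k-mer is among the s smallest
#' distinct hashes of at least one subsuming window.  At s = 1 this reduces
#' to the classic minimizer scheme.  \code{minimizerPositions} computes
#' w-minimizer positions directly (leftmost tie-break), as the comparison
#' baseline.
#'
#' @inheritParams buildMinmerIndex
#' @return Sorted integer vector of 0-based k-mer positions.
#' @examples
#' hs <- hashSequence(runif(50))
#' minmerPositions(hs, w = 10, s = 3)
#' @export
minmerPositions <- function(hseq, w, s) {
  idx <- buildMinmerIndex(hseq, w, s)
  sort(unique(idx@pos))
}

#' @rdname minmerPositions
#' @export
minimizerPositions <- function(hseq, w) {
  stopifnot(is(hseq, "HashSequence"))
  cpp_minimizer_positions(hseq@hashes, as.integer(w))
}

#' Check the (w, s)-window guarantee
#'
#' Verifies that every window of w k-mers contains at least
#' \code{min(#distinct, s)} sampled positions, where #distinct counts the
#' distinct unmasked hashes of the window.
#'
#' @param positions integer vector of sampled 0-based positions.
#' @inheritParams buildMinmerIndex
#' @return A list with \code{ok} (logical) and \code{window}: the first
#'   violating window start, or -1 when the guarantee holds.
#' @export
checkWindowGuarantee <- function(positions, hseq, w, s) {
  stopifnot(is(hseq, "HashSequence"))
  n <- length(hseq@hashes)
  sampled <- logical(n)
  sampled[positions + 1L] <- TRUE
  cpp_check_window_guarantee(hseq@hashes, sampled, as.integer(w),
                             as.integer(s))
}

#' Empirical density and density factor of a winnowing scheme
#'
#' Density is the fraction of k-mer positions sampled; the density factor is
#' the expected number of sampled positions in a window of w + 1 k-mers,
#' i.e. density * (w + 1).  A random-ordering minimizer scheme has density
#' factor 2 in the large-w limit.
#'
#' @param positions sampled positions (any vector; only its length is used).
#' @param n number of k-mer positions in the sequence.
#' @param w window length in k-mers.
#' @return A single numeric value.
#' @examples
#' empiricalDensityFactor(seq(0, 999, by = 50), n = 1000, w = 100)
#' @export
empiricalDensity <- function(positions, n) {
  stopifnot(n > 0)
  length(positions) / n
}

#' @rdname empiricalDensity
#' @export
empiricalDensityFactor <- function(positions, n, w) {
  empiricalDensity(positions, n) * (w + 1)
}
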