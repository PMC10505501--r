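#' @import methods
NULL

#' HashSequence: a sequence of k-mer hash values
#'
#' Represents a DNA sequence (or a synthetic hash stream) as the sequence of
#' hash values of its k-mers, one value per k-mer start position.  Positions
#' whose k-mer contains an ambiguous base (N) are masked and carry \code{NA}.
#' Hash values live in [0, 1) and are a deterministic function of
#' (sequence, k, seed, canonical).
#'
#' @slot hashes numeric vector of per-position hash values (\code{NA} = masked).
#' @slot k k-mer length in bases (1 for raw hash streams).
#' @slot seed integer seed of the hash function.
#' @slot canonical logical; whether k-mers were strand-canonicalized.
#' @slot orientations logical vector parallel to \code{hashes}: \code{TRUE}
#'   when the canonical spelling equals the forward spelling (\code{NA} for
#'   masked positions or raw hash streams).
#' @slot sourceName identifier of the source sequence.
#'
#' @exportClass HashSequence
setClass("HashSequence",
  representation(
    hashes = "numeric",
    k = "integer",
    seed = "integer",
    canonical = "logical",
    orientations = "logical",
    sourceName = "character"
  ),
  prototype(
    hashes = numeric(0), k = 1L, seed = 42L, canonical = TRUE,
    orientations = logical(0), sourceName = "unnamed"
  ),
  validity = function(object) {
    msg <- NULL
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
      msg <- c(msg, "k must be a single positive integer")
    if (length(object@orientations) != 0L &&
        length(object@orientations) != length(object@hashes))
      msg <- c(msg, "orientations must be empty or parallel to hashes")
    if (any(object@hashes < 0 | object@hashes > 1, na.rm = TRUE))
      msg <- c(msg, "hash values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' BottomSketch: the s smallest distinct hash values of a k-mer set
#'
#' @slot hashes strictly increasing numeric vector,
#'   \code{length(hashes) == min(s, number of distinct input hashes)}.
#' @slot s nominal sketch size.
#' @slot orientations logical vector parallel to \code{hashes} giving the
#'   strand orientation bit of the (leftmost occurrence of the) k-mer behind
#'   each hash; may be empty for raw hash streams.
#'
#' @exportClass BottomSketch
setClass("BottomSketch",
  representation(hashes = "numeric", s = "integer", orientations = "logical"),
  prototype(hashes = numeric(0), s = 1L, orientations = logical(0)),
  validity = function(object) {
    msg <- NULL
    if (length(object@s) != 1L || is.na(object@s) || object@s < 1L)
      msg <- c(msg, "s must be a single positive integer")
    if (is.unsorted(object@hashes, strictly = TRUE))
      msg <- c(msg, "sketch hashes must be strictly increasing")
    if (length(object@hashes) > object@s)
      msg <- c(msg, "sketch holds more than s hashes")
    if (length(object@orientations) != 0L &&
        length(object@orientations) != length(object@hashes))
      msg <- c(msg, "orientations must be empty or parallel to hashes")
    if (is.null(msg)) TRUE else msg
  }
)

#' MinmerIndex: sorted minmer-interval index of a reference sequence
#'
#' A minmer interval (i, a, b) records that the k-mer at position i belongs to
#' the bottom-s sketch of every window Wj with window start j in [a, b).
#' Intervals are stored sorted by start; a hash-ordered permutation supports
#' the reverse lookup from hash values to their intervals.  For every window
#' start j, the hashes of the intervals containing j are exactly the s
#' smallest distinct hashes of that window, which is what makes the index an
#' exact rolling bottom-s sketch.
#'
#' @slot hash,pos,start,end parallel interval columns (0-based; [start, end)
#'   in window-start coordinates; pos is the k-mer position).
#' @slot orient per-interval strand orientation bit of the k-mer occurrence.
#' @slot hashOrder permutation of intervals ordered by (hash, start).
#' @slot w,s,k winnowing parameters (window length in k-mers, sketch size,
#'   k-mer length).
#' @slot seed,canonical hashing parameters.
#' @slot n number of k-mers in the reference.
#' @slot nWindows number of windows (\code{max(1, n - w + 1)}).
#' @slot refName,refLength reference identifier and length in bases.
#' @slot heapPrunes number of heap prunes performed during construction
#'   (diagnostic for the amortized O(1) prune bound).
#'
#' @exportClass MinmerIndex
setClass("MinmerIndex",
  representation(
    hash = "numeric", pos = "integer", start = "integer", end = "integer",
    orient = "logical", hashOrder = "integer",
    w = "integer", s = "integer", k = "integer",
    seed = "integer", canonical = "logical",
    n = "integer", nWindows = "integer",
    refName = "character", refLength = "integer",
    heapPrunes = "integer"
  ),
  validity = function(object) {
    m <- length(object@hash)
    msg <- NULL
    if (length(object@pos) != m || length(object@start) != m ||
        length(object@end) != m || length(object@orient) != m ||
        length(object@hashOrder) != m)
      msg <- c(msg, "interval columns must have equal length")
    if (m > 0L) {
      if (any(object@start >= object@end))
        msg <- c(msg, "intervals must satisfy start < end")
      if (any(object@end - object@start > object@w))
        msg <- c(msg, "intervals longer than w must be split")
      if (is.unsorted(object@start))
        msg <- c(msg, "intervals must be sorted by start")
    }
    if (object@s < 1L || object@s > object@w)
      msg <- c(msg, "need 1 <= s <= w")
    if (is.null(msg)) TRUE else msg
  }
)

#' MapParams: parameters of the two-stage mapping algorithm
#'
#' @slot aniThreshold minimum ANI of reported mappings (default 0.85).
#' @slot deltaAni report (and protect from filtering) mappings within
#'   \code{deltaAni} of the best mapping's ANI (default 0: best only).
#' @slot filterConfidence retention confidence of the hypergeometric Stage-1
#'   filter: a candidate region is kept when the probability that its minhash
#'   numerator reaches the (best ANI - deltaAni) level is at least
#'   \code{filterConfidence}'s complement quantile; see the vignette.
#' @slot reportAll report all mappings within deltaAni of the best instead of
#'   the single best per query segment.
#' @slot earlyTermination stop Stage 2 once no remaining candidate region can
#'   contain a mapping within deltaAni of the best (lossless; default TRUE).
#' @slot minSegmentFraction retain a final partial query segment only when it
#'   holds at least this fraction of w k-mers (default 0.5).
#'
#' @exportClass MapParams
setClass("MapParams",
  representation(
    aniThreshold = "numeric", deltaAni = "numeric",
    filterConfidence = "numeric", reportAll = "logical",
    earlyTermination = "logical", minSegmentFraction = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (object@aniThreshold <= 0 || object@aniThreshold > 1)
      msg <- c(msg, "aniThreshold must lie in (0, 1]")
    if (object@deltaAni < 0) msg <- c(msg, "deltaAni must be >= 0")
    if (object@filterConfidence <= 0 || object@filterConfidence > 1)
      msg <- c(msg, "filterConfidence must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "HashSequence", function(object) {
  n <- length(object@hashes)
  cat("HashSequence '", object@sourceName, "': ", n, " k-mers (k=", object@k,
      ", seed=", object@seed,
      if (object@canonical) ", canonical" else "", ")",
      if (anyNA(object@hashes))
        paste0(", ", sum(is.na(object@hashes)), " masked") else "",
      "\n", sep = "")
})

setMethod("show", "BottomSketch", function(object) {
  cat("BottomSketch: ", length(object@hashes), "/", object@s,
      " hashes", "\n", sep = "")
})

setMethod("show", "MinmerIndex", function(object) {
  m <- length(object@hash)
  cat("MinmerIndex of '", object@refName, "' (n=", object@n, " k-mers, w=",
      object@w, ", s=", object@s, ", k=", object@k, ")\n", sep = "")
  cat("  ", m, " minmer intervals over ", length(unique(object@pos)),
      " sampled positions (interval density ",
      signif(m / max(1L, object@n), 4), ")\n", sep = "")
})

setMethod("show", "MapParams", function(object) {
  cat("MapParams: aniThreshold=", object@aniThreshold,
      ", deltaAni=", object@deltaAni,
      ", filterConfidence=", object@filterConfidence,
      ", reportAll=", object@reportAll,
      ", earlyTermination=", object@earlyTermination, "\n", sep = "")
})
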