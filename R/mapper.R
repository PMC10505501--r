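#' Mapping parameters
#'
#' Constructor for \linkS4class{MapParams}, the knobs of the two-stage
#' mapping algorithm.  Defaults: report the single best mapping per query
#' segment above 85% ANI, with the hypergeometric Stage-1 filter at
#' retention confidence 0.999 and lossless early termination of Stage 2.
#'
#' @param aniThreshold minimum ANI of reported mappings.
#' @param deltaAni report mappings within this ANI distance of the best.
#' @param filterConfidence Stage-1 retention confidence (see vignette).
#' @param reportAll report all mappings within \code{deltaAni} of the best.
#' @param earlyTermination lossless early stop of Stage 2.
#' @param minSegmentFraction minimum fraction of w k-mers for a final
#'   partial query segment to be mapped.
#' @return A \linkS4class{MapParams} object.
#' @examples
#' mapParams(aniThreshold = 0.9, deltaAni = 0.02, reportAll = TRUE)
#' @export
mapParams <- function(aniThreshold = 0.85, deltaAni = 0,
                      filterConfidence = 0.999, reportAll = FALSE,
                      earlyTermination = TRUE, minSegmentFraction = 0.5) {
  new("MapParams", aniThreshold = aniThreshold, deltaAni = deltaAni,
      filterConfidence = filterConfidence, reportAll = isTRUE(reportAll),
      earlyTermination = isTRUE(earlyTermination),
      minSegmentFraction = minSegmentFraction)
}

.emptyMappings <- function() {
  data.frame(query = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), target = character(0),
             tlen = integer(0), tstart = integer(0), tend = integer(0),
             numerator = integer(0), denominator = integer(0),
             jaccard = numeric(0), ani = numeric(0), complexity = numeric(0))
}

#' Sweep matched intervals into candidate regions
#'
#' Given the [start, end) window-start ranges of matched minmer intervals
#' (one merged range set per distinct hash), sweeps the sorted endpoint list
#' while keeping a running overlap count, and returns the maximal runs where
#' the count reaches \code{minCount}, annotated with the maximum
#' simultaneous overlap ci reached inside each run.
#'
#' @param starts,ends integer vectors of interval endpoints (half-open).
#' @param minCount minimum overlap count for a region.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{maxOverlap}.
#' @examples
#' sweepCandidateRegions(c(2, 5, 6), c(7, 9, 8), minCount = 3)
#' @export
sweepCandidateRegions <- function(starts, ends, minCount) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      maxOverlap = integer(0))
  if (!length(starts)) return(empty)
  stopifnot(length(starts) == length(ends), all(starts < ends),
            minCount >= 1)
  pts <- sort(unique(c(starts, ends)))
  delta <- tabulate(match(starts, pts), length(pts)) -
    tabulate(match(ends, pts), length(pts))
  cum <- cumsum(delta)  # overlap count on segment [pts[i], pts[i+1])
  qual <- cum >= minCount
  if (!any(qual)) return(empty)
  r <- rle(qual)
  segEnd <- cumsum(r$lengths)
  segStart <- segEnd - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = pts[segStart[keep]],
    end = pts[segEnd[keep] + 1L],
    maxOverlap = vapply(keep, function(i)
      max(cum[segStart[i]:segEnd[i]]), integer(1))
  )
}

# merged [start, end) runs of the intervals matching each query-sketch hash;
# returns list(starts, ends, hashFirstIdx) with one merged run set per hash
.matchedRuns <- function(querySketch, index) {
  qs <- querySketch@hashes
  ho <- index@hashOrder
  sh <- index@hash[ho]
  lastIdx <- findInterval(qs, sh)
  firstIdx <- findInterval(qs, sh, left.open = TRUE) + 1L
  starts <- integer(0); ends <- integer(0)
  for (qi in seq_along(qs)) {
    if (firstIdx[qi] > lastIdx[qi]) next
    ids <- ho[firstIdx[qi]:lastIdx[qi]]    # ordered by start within hash
    if (sh[firstIdx[qi]] != qs[qi]) next   # no exact match
    ss <- index@start[ids]; ee <- index@end[ids]
    # merge overlapping or adjacent runs so each hash counts once per window
    cs <- ss[1]; ce <- ee[1]
    for (t in seq_along(ss)[-1]) {
      if (ss[t] <= ce) ce <- max(ce, ee[t])
      else { starts <- c(starts, cs); ends <- c(ends, ce); cs <- ss[t]; ce <- ee[t] }
    }
    starts <- c(starts, cs); ends <- c(ends, ce)
  }
  list(starts = starts, ends = ends)
}

#' Stage 1: candidate region filter
#'
#' Looks up the reference minmer intervals whose hashes belong to the query
#' sketch, and sweeps their sorted endpoints to find all window-start
#' regions where at least \code{minCount} sketch hashes are simultaneously
#' in the window's bottom-s sketch.  The overlap count at window start j
#' equals the sketch intersection size |pi_s(A) n pi_s(B_j)|, an upper
#' bound on the minhash numerator, so every position that can reach the ANI
#' threshold lies inside a returned region.
#'
#' @param querySketch \linkS4class{BottomSketch} of the query segment, built
#'   with the index's (k, seed, s).
#' @param index a \linkS4class{MinmerIndex}.
#' @param params a \linkS4class{MapParams}; its \code{aniThreshold} implies
#'   the minimum numerator.
#' @param minCount optional explicit overlap threshold overriding the
#'   ANI-derived one.
#' @return data.frame with columns \code{refName}, \code{start}, \code{end},
#'   \code{maxOverlap} (ci <= s).
#' @export
stage1Candidates <- function(querySketch, index, params = mapParams(),
                             minCount = NULL) {
  stopifnot(is(querySketch, "BottomSketch"), is(index, "MinmerIndex"))
  empty <- data.frame(refName = character(0), start = integer(0),
                      end = integer(0), maxOverlap = integer(0))
  sEff <- length(querySketch@hashes)
  if (!sEff) return(empty)
  if (is.null(minCount)) {
    jmin <- aniToJaccard(params@aniThreshold, index@k)
    minCount <- max(1L, as.integer(ceiling(sEff * jmin - 1e-9)))
  }
  runs <- .matchedRuns(querySketch, index)
  reg <- sweepCandidateRegions(runs$starts, runs$ends, minCount)
  if (!nrow(reg)) return(empty)
  cbind(refName = index@refName, reg)
}

#' Hypergeometric distribution of the minhash numerator
#'
#' Conditioned on the sketch intersection size c = |pi_s(A) n pi_s(B)|, the
#' minhash numerator Y (shared members captured by the bottom-s of the
#' union of two size-s sketches) is hypergeometric: a draw of s from a
#' population of 2s - c values of which c are shared.
#'
#' @param s sketch size.
#' @param c sketch intersection size, \code{0 <= c <= s}.
#' @return data.frame with columns \code{y} (0..c) and \code{p}.
#' @examples
#' minhashNumeratorPmf(10, 10)   # identical sketches: Y = s surely
#' @export
minhashNumeratorPmf <- function(s, c) {
  stopifnot(s >= 1, c >= 0, c <= s)
  y <- 0:c
  data.frame(y = y, p = stats::dhyper(y, c, 2 * (s - c), s))
}

#' Stage-1 probabilistic filter on candidate regions
#'
#' Drops candidate regions that are unlikely to contain a mapping within
#' \code{deltaAni} of the best candidate's ANI.  The best region's ANI is
#' estimated conservatively as the ANI of the (1 - filterConfidence)
#' quantile of its numerator distribution; kappa is the numerator
#' corresponding to that ANI minus \code{deltaAni}; a region with maximum
#' overlap ci is kept iff Pr(Y >= kappa | ci) >= filterConfidence.
#' Regions with ci < kappa have Pr(Y >= kappa) = 0 and are always dropped.
#'
#' @param regions data.frame from \code{\link{stage1Candidates}}.
#' @param params a \linkS4class{MapParams}.
#' @param s sketch size used for the query.
#' @param k k-mer length (for the Jaccard-ANI conversion).
#' @return The filtered subset of \code{regions}.
#' @export
deltaAniPrefilter <- function(regions, params, s, k) {
  if (!nrow(regions)) return(regions)
  cBest <- max(regions$maxOverlap)
  yLo <- stats::qhyper(1 - params@filterConfidence, cBest, 2 * (s - cBest), s)
  bestAniLo <- jaccardToAni(yLo / s, k)
  target <- max(bestAniLo - params@deltaAni, 0)
  kap <- max(0, ceiling(s * aniToJaccard(target, k) - 1e-9))
  prReach <- stats::phyper(kap - 1, regions$maxOverlap,
                           2 * (s - regions$maxOverlap), s,
                           lower.tail = FALSE)
  regions[prReach >= params@filterConfidence - 1e-12, , drop = FALSE]
}

#' Stage 2: rolling minhash over a candidate region
#'
#' Computes the minhash numerator, denominator and Jaccard estimate of the
#' query sketch against every reference window in [start, end) of a
#' candidate region.  A static array of query-sketch slots tracks matched
#' hashes and the counts of reference-sketch hashes between consecutive
#' query hashes; interval starts and ends drive O(log s) updates as the
#' window slides.  The output is value-identical to evaluating
#' \code{minhashJaccard(querySketch, windowSketch(index, i))} at every i.
#'
#' @param querySketch \linkS4class{BottomSketch} of the query segment.
#' @param index a \linkS4class{MinmerIndex}.
#' @param region a row of \code{\link{stage1Candidates}} output, or a
#'   numeric vector \code{c(start, end)} of window starts.
#' @return data.frame with columns \code{pos}, \code{numerator},
#'   \code{denominator}, \code{jaccard}.
#' @export
stage2RollingMinhash <- function(querySketch, index, region) {
  stopifnot(is(querySketch, "BottomSketch"), is(index, "MinmerIndex"))
  if (is.data.frame(region)) {
    a <- region$start[1L]; z <- region$end[1L]
  } else {
    a <- region[1L]; z <- region[2L]
  }
  a <- as.integer(a); z <- as.integer(min(z, index@nWindows))
  if (a < 0L || a >= z) stop("candidate region out of range")
  if (querySketch@s != index@s)
    stop("query sketch size must match the index sketch size")
  starts <- index@start
  lastI <- findInterval(z - 0.5, starts)
  firstI <- findInterval(a - index@w - 0.5, starts) + 1L
  sel <- if (lastI >= firstI) firstI:lastI else integer(0)
  sel <- sel[index@end[sel] > a]
  res <- cpp_stage2_rolling(querySketch@hashes, index@hash[sel],
                            index@start[sel], index@end[sel], a, z,
                            querySketch@s)
  data.frame(pos = res$pos, numerator = res$numerator,
             denominator = res$denominator,
             jaccard = res$numerator / pmax(res$denominator, 1L))
}

# majority vote over matched sketch hashes at reference window `pos`:
# "-" when most matched k-mers flip canonical orientation between query
# and reference
.strandVote <- function(index, querySketch, pos) {
  if (!length(querySketch@orientations)) return("+")
  sel <- which(index@start <= pos & index@end > pos)
  h <- index@hash[sel]; o <- index@orient[sel]
  first <- !duplicated(h)
  h <- h[first]; o <- o[first]
  mi <- match(h, querySketch@hashes)
  ok <- !is.na(mi)
  if (!any(ok)) return("+")
  qo <- querySketch@orientations[mi[ok]]
  ro <- o[ok]
  keep <- !is.na(qo) & !is.na(ro)
  if (!any(keep)) return("+")
  if (sum(qo[keep] != ro[keep]) > sum(qo[keep] == ro[keep])) "-" else "+"
}

#' Map a query sequence against a minmer index
#'
#' Splits the query into segments of w k-mers (a final partial segment is
#' retained when it holds at least \code{minSegmentFraction * w} k-mers, or
#' when it is the only segment), sketches each segment, and runs the
#' two-stage mapping: Stage 1 collects candidate regions by interval
#' sweeping with the hypergeometric ANI filter; Stage 2 computes the rolling
#' minhash over each region in decreasing order of maximum interval overlap,
#' stopping (losslessly) once no remaining region can reach within
#' \code{deltaAni} of the best ANI seen.  Per region the best window is
#' retained; mappings below \code{aniThreshold} are dropped, and either the
#' single best or all mappings within \code{deltaAni} of the best are
#' reported.  Strand is called by majority vote over the canonical
#' orientation bits of matched sketch k-mers.
#'
#' @param query a character string, \code{DNAString}, or length-1
#'   \code{DNAStringSet}; raw \linkS4class{HashSequence} inputs are also
#'   accepted (strand and complexity then refer to hash positions).
#' @param index a \linkS4class{MinmerIndex} built from the reference.
#' @param params a \linkS4class{MapParams}.
#' @param queryName identifier for the output (defaults to the input name).
#' @return data.frame with one row per reported mapping: \code{query},
#'   \code{qlen}, \code{qstart}, \code{qend} (bp, 0-based half-open),
#'   \code{strand}, \code{target}, \code{tlen}, \code{tstart}, \code{tend},
#'   \code{numerator}, \code{denominator}, \code{jaccard}, \code{ani},
#'   \code{complexity} (distinct k-mers / segment length).
#' @examples
#' ref <- randomDna(3000, seed = 7)
#' idx <- buildMinmerIndex(kmerHashSequence(ref, k = 15), w = 500, s = 20)
#' qry <- substr(ref, 1001, 2200)
#' mapQuery(qry, idx, mapParams(aniThreshold = 0.9))
#' @export
mapQuery <- function(query, index, params = mapParams(), queryName = NULL) {
  stopifnot(is(index, "MinmerIndex"), is(params, "MapParams"))
  if (is(query, "HashSequence")) {
    hq <- query
    if (!is.null(queryName)) hq@sourceName <- queryName
  } else {
    hq <- kmerHashSequence(query, k = index@k, seed = index@seed,
                           canonical = index@canonical, name = queryName)
  }
  nq <- length(hq@hashes)
  if (nq < 1L) {
    warning("query shorter than k: no k-mers to map")
    return(.emptyMappings())
  }
  w <- index@w
  k <- index@k
  qlenBp <- nq + if (k > 1L) k - 1L else 0L
  if (nq <= w) {
    segs <- list(c(0L, nq))
  } else {
    full <- nq %/% w
    segs <- lapply(seq_len(full), function(t) c((t - 1L) * w, t * w))
    rem <- nq - full * w
    if (rem >= params@minSegmentFraction * w)
      segs <- c(segs, list(c(full * w, nq)))
  }
  out <- list()
  for (seg in segs) {
    a <- seg[1L]; b <- seg[2L]
    hseg <- new("HashSequence", hashes = hq@hashes[(a + 1L):b],
                k = k, seed = hq@seed, canonical = hq@canonical,
                orientations = if (length(hq@orientations))
                  hq@orientations[(a + 1L):b] else logical(0),
                sourceName = hq@sourceName)
    qsk <- bottomSketch(hseg, index@s)
    sEff <- length(qsk@hashes)
    if (!sEff) next
    complexity <- length(unique(hseg@hashes[!is.na(hseg@hashes)])) / (b - a)
    regions <- stage1Candidates(qsk, index, params)
    if (!nrow(regions)) next
    regions <- deltaAniPrefilter(regions, params, s = sEff, k = k)
    if (!nrow(regions)) next
    regions <- regions[order(-regions$maxOverlap, regions$start), ,
                       drop = FALSE]
    best <- 0
    cand <- list()
    for (ri in seq_len(nrow(regions))) {
      if (params@earlyTermination && best > 0) {
        kap <- max(0, ceiling(
          sEff * aniToJaccard(max(best - params@deltaAni, 0), k) - 1e-9))
        if (regions$maxOverlap[ri] < kap) break
      }
      st2 <- stage2RollingMinhash(qsk, index, regions[ri, ])
      bi <- which.max(st2$jaccard)  # leftmost on ties
      ani <- jaccardToAni(st2$jaccard[bi], k)
      best <- max(best, ani)
      cand[[length(cand) + 1L]] <-
        data.frame(pos = st2$pos[bi], numerator = st2$numerator[bi],
                   denominator = st2$denominator[bi],
                   jaccard = st2$jaccard[bi], ani = ani)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[cand$ani >= params@aniThreshold - 1e-9, , drop = FALSE]
    if (!nrow(cand)) next
    bestAni <- max(cand$ani)
    if (params@reportAll) {
      cand <- cand[cand$ani >= bestAni - params@deltaAni - 1e-9, ,
                   drop = FALSE]
      cand <- cand[order(-cand$ani, cand$pos), , drop = FALSE]
    } else {
      cand <- cand[order(-cand$ani, cand$pos)[1L], , drop = FALSE]
    }
    for (ci in seq_len(nrow(cand))) {
      pos <- cand$pos[ci]
      out[[length(out) + 1L]] <- data.frame(
        query = hq@sourceName, qlen = qlenBp,
        qstart = a, qend = b + if (k > 1L) k - 1L else 0L,
        strand = .strandVote(index, qsk, pos),
        target = index@refName, tlen = index@refLength,
        tstart = pos,
        tend = min(pos + w + if (k > 1L) k - 1L else 0L, index@refLength),
        numerator = cand$numerator[ci], denominator = cand$denominator[ci],
        jaccard = cand$jaccard[ci], ani = cand$ani[ci],
        complexity = complexity)
    }
  }
  if (!length(out)) return(.emptyMappings())
  res <- do.call(rbind, out)
  res[order(res$qstart, res$tstart), , drop = FALSE]
}

#' Write mappings in PAF-like format
#'
#' Tab-separated records: query, qlen, qstart, qend, strand, target, tlen,
#' tstart, tend, numerator, denominator, 255, plus \code{id:f:} (ANI),
#' \code{jc:f:} (Jaccard) and \code{cm:f:} (complexity) tags.
#'
#' @param mappings data.frame from \code{\link{mapQuery}}.
#' @param path output file path ("" for stdout).
#' @return The path, invisibly.
#' @export
writePaf <- function(mappings, path = "") {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255\tid:f:%.6f\tjc:f:%.6f\tcm:f:%.4f",
                   mappings$query, mappings$qlen, mappings$qstart,
                   mappings$qend, mappings$strand, mappings$target,
                   mappings$tlen, mappings$tstart, mappings$tend,
                   mappings$numerator, mappings$denominator, mappings$ani,
                   mappings$jaccard, mappings$complexity)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(path)
}

#' Minimizer-based winnowed minhash (biased baseline)
#'
#' The estimator used by minimizer-based mappers: winnow both sequences
#' with a w-minimizer scheme, then apply the bottom-s minhash estimator to
#' the minimizer hash sets.  Unlike the minmer estimator this is a biased
#' estimator of the k-mer-set Jaccard (it systematically under-predicts
#' ANI); it is provided as the comparison baseline.
#'
#' @param hseqA,hseqB \linkS4class{HashSequence} objects (same k and seed).
#' @param w minimizer window length in k-mers.
#' @param s sketch size for the minhash estimator; \code{NULL} (default)
#'   compares the full winnowed sets (sketch size = the smaller minimizer
#'   count), as minimizer-based MashMap does.
#' @return A list with \code{jaccard}, \code{numerator}, \code{denominator}.
#' @export
winnowedMinhashJaccard <- function(hseqA, hseqB, w, s = NULL) {
  pa <- minimizerPositions(hseqA, w)
  pb <- minimizerPositions(hseqB, w)
  ha <- hseqA@hashes[pa + 1L]
  hb <- hseqB@hashes[pb + 1L]
  if (is.null(s))
    s <- min(length(unique(ha[!is.na(ha)])), length(unique(hb[!is.na(hb)])))
  minhashJaccard(bottomSketch(ha, s), bottomSketch(hb, s))
}
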