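#' Accessors for package classes
#'
#' \code{hashValues} returns the per-position hash vector of a
#' \linkS4class{HashSequence} or the sorted hashes of a
#' \linkS4class{BottomSketch}; \code{kmerSize} the k-mer length;
#' \code{sourceName} the sequence identifier; \code{sketchSize} the nominal
#' sketch size; \code{minmerIntervals} the interval table of a
#' \linkS4class{MinmerIndex} as a data.frame; \code{windowCount} its number
#' of windows; \code{winnowParams} its (w, s, k) parameter list.
#'
#' @param x an object of the documented class.
#' @return See the description of the individual accessor.
#' @name accessors
#' @examples
#' hs <- kmerHashSequence("ACGTACGTAC", k = 4)
#' hashValues(hs)
#' kmerSize(hs)
NULL

#' @rdname accessors
#' @export
setGeneric("hashValues", function(x) standardGeneric("hashValues"))

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname accessors
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))

#' @rdname accessors
#' @export
setGeneric("sketchSize", function(x) standardGeneric("sketchSize"))

#' @rdname accessors
#' @export
setGeneric("minmerIntervals", function(x) standardGeneric("minmerIntervals"))

#' @rdname accessors
#' @export
setGeneric("windowCount", function(x) standardGeneric("windowCount"))

#' @rdname accessors
#' @export
setGeneric("winnowParams", function(x) standardGeneric("winnowParams"))

#' Bottom-s sketching
#'
#' Returns the \code{s} smallest distinct hash values of the input as a
#' \linkS4class{BottomSketch}.  Duplicate values collapse (k-mer sets are
#' sets); masked (\code{NA}) positions are ignored.  If fewer than \code{s}
#' distinct values exist, all of them are returned.
#'
#' @param x numeric hash values or a \linkS4class{HashSequence}.
#' @param s sketch size (positive integer).
#' @return A \linkS4class{BottomSketch}.
#' @examples
#' bottomSketch(c(0.5, 0.1, 0.9, 0.3), s = 2)
#' @export
setGeneric("bottomSketch", function(x, s) standardGeneric("bottomSketch"))

#' @rdname accessors
#' @export
setMethod("hashValues", "HashSequence", function(x) x@hashes)

#' @rdname accessors
#' @export
setMethod("hashValues", "BottomSketch", function(x) x@hashes)

#' @rdname accessors
#' @export
setMethod("kmerSize", "HashSequence", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("kmerSize", "MinmerIndex", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sourceName", "HashSequence", function(x) x@sourceName)

#' @rdname accessors
#' @export
setMethod("sketchSize", "BottomSketch", function(x) x@s)

#' @rdname accessors
#' @export
setMethod("sketchSize", "MinmerIndex", function(x) x@s)

#' @rdname accessors
#' @export
setMethod("minmerIntervals", "MinmerIndex", function(x) {
  data.frame(hash = x@hash, pos = x@pos, start = x@start, end = x@end,
             orient = x@orient)
})

#' @rdname accessors
#' @export
setMethod("windowCount", "MinmerIndex", function(x) x@nWindows)

#' @rdname accessors
#' @export
setMethod("winnowParams", "MinmerIndex", function(x) {
  list(w = x@w, s = x@s, k = x@k, seed = x@seed, canonical = x@canonical)
})

setMethod("length", "HashSequence", function(x) length(x@hashes))
setMethod("length", "BottomSketch", function(x) length(x@hashes))
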