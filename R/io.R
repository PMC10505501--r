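#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings' multi-record FASTA support (wrapped or
#' unwrapped lines, case-insensitive alphabet).
#'
#' @param path file path.
#' @param x a \link[Biostrings]{DNAStringSet} or a named character vector.
#' @param width line width for writing.
#' @return \code{readFasta}: a \code{DNAStringSet}; \code{writeFasta}: the
#'   path, invisibly.
#' @export
readFasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' @rdname readFasta
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
    names(x) <- nm
  }
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Serialize a minmer index to a tabular file
#'
#' Writes a plain-text, tab-separated representation: header comment lines
#' carrying (w, s, k, seed, canonical, ref_name, ref_length, n, heap_prunes),
#' followed by one (hash, pos, start, end, orient) record per interval,
#' sorted by start.  Hashes are printed with 17 significant digits so the
#' round trip through text is exact.
#'
#' @param index a \linkS4class{MinmerIndex}.
#' @param path file path.
#' @return \code{writeMinmerIndex}: the path, invisibly;
#'   \code{readMinmerIndex}: a \linkS4class{MinmerIndex} identical to the
#'   one written.
#' @export
writeMinmerIndex <- function(index, path) {
  stopifnot(is(index, "MinmerIndex"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#minmer_index\tv1",
    sprintf("#w=%d\ts=%d\tk=%d\tseed=%d\tcanonical=%d\tref_name=%s\tref_length=%d\tn=%d\theap_prunes=%d",
            index@w, index@s, index@k, index@seed,
            as.integer(index@canonical), index@refName, index@refLength,
            index@n, index@heapPrunes),
    "#hash\tpos\tstart\tend\torient"), con)
  if (length(index@hash)) {
    lines <- sprintf("%.17g\t%d\t%d\t%d\t%d", index@hash, index@pos,
                     index@start, index@end, as.integer(index@orient))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname writeMinmerIndex
#' @export
readMinmerIndex <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!startsWith(hdr[1L], "#minmer_index"))
    stop("not a minmer index file: ", path)
  kv <- strsplit(sub("^#", "", hdr[2L]), "\t")[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  allLines <- readLines(path)
  dataLines <- allLines[!startsWith(allLines, "#")]
  if (length(dataLines)) {
    tab <- utils::read.table(text = dataLines, sep = "\t",
                             col.names = c("hash", "pos", "start", "end",
                                           "orient"),
                             colClasses = c("numeric", "integer", "integer",
                                            "integer", "integer"))
  } else {
    tab <- data.frame(hash = numeric(0), pos = integer(0), start = integer(0),
                      end = integer(0), orient = integer(0))
  }
  m <- nrow(tab)
  orient <- as.logical(tab$orient)
  new("MinmerIndex",
      hash = tab$hash, pos = tab$pos, start = tab$start, end = tab$end,
      orient = orient,
      hashOrder = if (m) order(tab$hash, tab$start) else integer(0),
      w = as.integer(vals[["w"]]), s = as.integer(vals[["s"]]),
      k = as.integer(vals[["k"]]), seed = as.integer(vals[["seed"]]),
      canonical = as.integer(vals[["canonical"]]) == 1L,
      n = as.integer(vals[["n"]]),
      nWindows = max(1L, as.integer(vals[["n"]]) - as.integer(vals[["w"]]) + 1L),
      refName = vals[["ref_name"]],
      refLength = as.integer(vals[["ref_length"]]),
      heapPrunes = as.integer(vals[["heap_prunes"]]))
}
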