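#' Hash the k-mers of a DNA sequence
#'
#' Converts a DNA sequence into a \linkS4class{HashSequence}: one hash value
#' per k-mer start position, computed with a seeded 64-bit mixing hash and
#' mapped to [0, 1).  With \code{canonical = TRUE} (the default) a k-mer and
#' its reverse complement hash identically: the lexicographically smaller of
#' the two spellings is hashed, so mapping is strand-symmetric.  Any k-mer
#' containing an N is masked (its position carries \code{NA}) and is invisible
#' to all downstream winnowing and sketching.
#'
#' @param seq a character string over A,C,G,T,N (case-insensitive), or a
#'   \link[Biostrings]{DNAString}, or a length-1 \code{DNAStringSet}.
#' @param k k-mer length in bases (1..31).
#' @param seed integer seed of the hash function.
#' @param canonical hash the canonical (strand-independent) spelling.
#' @param name sequence identifier; defaults to the input's name, if any.
#' @return A \linkS4class{HashSequence} with \code{length(seq) - k + 1}
#'   hashes (empty when the sequence is shorter than k).
#' @examples
#' hs <- kmerHashSequence("ACGTACGTAC", k = 4)
#' length(hs)
#' @export
kmerHashSequence <- function(seq, k, seed = 42L, canonical = TRUE,
                             name = NULL) {
  if (is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence; got a DNAStringSet of length ",
           length(seq))
    if (is.null(name)) name <- names(seq)
    seq <- seq[[1L]]
  }
  if (is(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single character string or DNAString")
  if (is.null(name) || !length(name)) name <- "unnamed"
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  if (k > 31L) stop("'k' must be at most 31")
  seed <- as.integer(seed)
  res <- cpp_kmer_hashes(seq, k, seed, isTRUE(canonical))
  new("HashSequence", hashes = res$hash, k = k, seed = seed,
      canonical = isTRUE(canonical), orientations = res$orient,
      sourceName = as.character(name))
}

#' Construct a HashSequence from raw hash values
#'
#' Wraps an arbitrary numeric vector of values in [0, 1) (NA = masked) as a
#' \linkS4class{HashSequence}, e.g. an i.i.d. uniform stream used to study
#' winnowing schemes under the ideal-hash assumption.
#'
#' @param hashes numeric vector in [0, 1), \code{NA} allowed.
#' @param name identifier.
#' @param k nominal k-mer size (defaults to 1 for synthetic streams).
#' @param seed seed annotation carried along for provenance.
#' @return A \linkS4class{HashSequence}.
#' @export
hashSequence <- function(hashes, name = "hash_stream", k = 1L, seed = 0L) {
  new("HashSequence", hashes = as.numeric(hashes), k = as.integer(k),
      seed = as.integer(seed), canonical = FALSE,
      orientations = rep(NA, length(hashes)), sourceName = name)
}
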