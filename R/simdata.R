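# run expr with a local RNG seed, restoring global .Random.seed afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic i.i.d. uniform hash stream
#'
#' Generates n independent Uniform(0, 1) hash values wrapped as a
#' \linkS4class{HashSequence} -- the ideal-hash model under which the
#' density and spread formulas of the minmer scheme are derived.
#'
#' @param n stream length.
#' @param seed RNG seed (all randomness flows from explicit seeds).
#' @return A \linkS4class{HashSequence} with k = 1.
#' @examples
#' randomHashStream(10, seed = 1)
#' @export
randomHashStream <- function(n, seed = 1L) {
  h <- .withSeed(seed, stats::runif(n))
  new("HashSequence", hashes = h, k = 1L, seed = as.integer(seed),
      canonical = FALSE, orientations = rep(NA, n),
      sourceName = sprintf("uniform_stream_n%d_seed%d", as.integer(n),
                           as.integer(seed)))
}

#' Random DNA sequence
#'
#' @param n sequence length in bases.
#' @param seed RNG seed.
#' @param gc GC content in [0, 1].
#' @return A single character string over ACGT.
#' @examples
#' randomDna(20, seed = 1)
#' @export
randomDna <- function(n, seed = 1L, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .withSeed(seed, paste(sample(names(p), n, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Point-mutate a sequence at a controlled divergence
#'
#' Substitutes exactly \code{round(rate * nchar(seq))} positions, chosen
#' uniformly without replacement, each to a different base drawn uniformly
#' from the three alternatives.  With \code{forbidDuplicateKmers} the
#' substitution set is resampled until no k-mer occurs twice within either
#' the original or the mutated sequence (the ideal-sequence model used to
#' study estimator bias), failing after \code{maxRetries} attempts.
#'
#' @param seq a character string over ACGT.
#' @param rate per-base substitution probability in [0, 1).
#' @param seed RNG seed.
#' @param k k-mer length used for the duplicate check.
#' @param forbidDuplicateKmers resample until both sequences are k-mer-unique.
#' @param maxRetries attempts before giving up.
#' @return A list with \code{sequence} (mutated string), \code{divergence}
#'   (exact realized fraction), \code{positions} (1-based), \code{refBase},
#'   \code{altBase}.
#' @examples
#' mutateSequence(randomDna(100, 1), rate = 0.05, seed = 2)$divergence
#' @export
mutateSequence <- function(seq, rate, seed = 1L, k = 19L,
                           forbidDuplicateKmers = FALSE, maxRetries = 50L) {
  stopifnot(is.character(seq), length(seq) == 1L, rate >= 0, rate < 1)
  n <- nchar(seq)
  m <- round(rate * n)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(seq, "")[[1]]
  hasDup <- function(x) {
    nk <- length(x) - k + 1L
    if (nk < 2L) return(FALSE)
    km <- substring(paste(x, collapse = ""), seq_len(nk), seq_len(nk) + k - 1L)
    anyDuplicated(km) > 0L
  }
  if (forbidDuplicateKmers && hasDup(ref))
    stop("input sequence already contains duplicate k-mers; ",
         "use a longer or random sequence")
  .withSeed(seed, {
    for (try in seq_len(maxRetries)) {
      mut <- ref
      pos <- integer(0)
      alt <- character(0)
      if (m > 0) {
        pos <- sort(sample.int(n, m))
        alt <- vapply(ref[pos], function(b)
          sample(setdiff(bases, b), 1L), "")
        mut[pos] <- alt
      }
      if (!forbidDuplicateKmers || !hasDup(mut)) {
        return(list(sequence = paste(mut, collapse = ""),
                    divergence = m / n,
                    positions = pos,
                    refBase = ref[pos],
                    altBase = unname(alt)))
      }
    }
    stop("could not avoid duplicate k-mers after ", maxRetries,
         " attempts; use a longer or more random sequence")
  })
}

#' Write a paired mutation fixture
#'
#' Emits the reference and its mutated copy as FASTA files plus a truth TSV
#' of (position, reference base, alternate base) with the realized
#' divergence in its header, for use as an external fixture.
#'
#' @param seq reference sequence (character).
#' @param rate,seed,k,forbidDuplicateKmers passed to
#'   \code{\link{mutateSequence}}.
#' @param prefix output path prefix; writes \code{<prefix>_ref.fa},
#'   \code{<prefix>_mut.fa}, \code{<prefix>_truth.tsv}.
#' @return Invisibly, the mutation record from \code{\link{mutateSequence}}.
#' @export
writeMutationFixture <- function(seq, rate, prefix, seed = 1L, k = 19L,
                                 forbidDuplicateKmers = FALSE) {
  rec <- mutateSequence(seq, rate, seed = seed, k = k,
                        forbidDuplicateKmers = forbidDuplicateKmers)
  writeFasta(c(ref = seq), paste0(prefix, "_ref.fa"))
  writeFasta(c(mut = rec$sequence), paste0(prefix, "_mut.fa"))
  con <- file(paste0(prefix, "_truth.tsv"), "wt")
  writeLines(sprintf("#divergence=%.10g", rec$divergence), con)
  writeLines("position\tref\talt", con)
  if (length(rec$positions))
    writeLines(sprintf("%d\t%s\t%s", rec$positions, rec$refBase,
                       rec$altBase), con)
  close(con)
  invisible(rec)
}
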