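#' minmer: minmer winnowing and unbiased local Jaccard estimation
#'
#' Minmers generalize minimizers by retaining the s smallest k-mer hashes of
#' every window of w k-mers.  Because the sampled set is a superset of every
#' window's bottom-s sketch, the minhash Jaccard estimator computed from a
#' minmer index is identical to the estimator on the full k-mer sets --
#' eliminating the bias of minimizer-based winnowed minhash -- while
#' retaining a (w, s)-window guarantee at a density well below that of a
#' window-matched minimizer scheme.  The package implements the rolling
#' interval index, the two-stage mapping algorithm with hypergeometric
#' candidate filtering, closed-form density/spread theory with simulation
#' validators, and seeded synthetic-data generators.
#'
#' @name minmer-package
#' @aliases minmer
#' @useDynLib minmer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dhyper phyper qhyper runif setNames
#' @importFrom utils read.table
"_PACKAGE"
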