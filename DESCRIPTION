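Package: minmer
Title: Minmer Winnowing and Unbiased Local Jaccard Estimation for Sequence Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the minmer winnowing scheme, a non-forward
    generalization of minimizers that retains the s smallest k-mer hashes of
    every w-long window. Minmer intervals support a rolling bottom-s minhash
    index over a reference genome, from which the bottom-s sketch of any
    window can be recovered exactly, yielding an unbiased estimator of the
    local Jaccard similarity and hence of average nucleotide identity (ANI).
    The package provides the rolling index construction, a two-stage
    approximate mapping algorithm with hypergeometric candidate filtering and
    early termination, closed-form density and spread characterizations of
    the scheme with Monte-Carlo validators, and synthetic-data generators
    (uniform hash streams, random DNA, point-mutated copies at controlled
    divergence) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Sequencing, Alignment, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'hashing.R'
    'sketch.R'
    'winnow.R'
    'io.R'
    'theory.R'
    'simdata.R'
    'mapper.R'
    'zzz.R'
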