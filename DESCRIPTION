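Package: patternHMM
Title: Hidden Markov Model Decoding Restricted to Pattern Occurrence Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical hidden Markov model (HMM) algorithms (forward,
    backward, Viterbi, posterior decoding, posterior-Viterbi) together with
    their pattern-restricted counterparts. A pattern is a regular expression
    over the hidden-state alphabet, tracked with a deterministic finite
    automaton run in parallel with the HMM. The restricted forward algorithm
    yields the posterior distribution of the number of pattern occurrences in
    the hidden sequence; restricted Viterbi and restricted posterior-Viterbi
    produce decodings whose occurrence count is constrained to a given
    interval, for example the posterior expectation. Includes a seven-state
    gene-finder example model, simulation drivers, and nucleotide- and
    gene-level evaluation measures for comparing decodings to a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    yaml,
    seqinr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
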