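#' The seven-state gene-finder model
#'
#' A small HMM for prokaryote-style gene finding over the DNA alphabet
#' `{A, C, G, T}`. The hidden states are a noncoding state `N` (self-looping),
#' a three-state codon cycle `C1 -> C2 -> C3 -> C1` for genes on the forward
#' strand, and a mirrored cycle for genes on the reverse strand. A
#' reverse-strand gene is read right-to-left, so in sequence order its codon
#' positions appear backwards: `N` enters at `R3`, the cycle runs
#' `R3 -> R2 -> R1 -> R3`, and the gene's start codon position `R1` exits to
#' `N` at the right edge. Consequently `N C1` marks a forward gene start and
#' `R1 N` a reverse gene start, so the pattern `(N C1)|(R1 N)` counts gene
#' starts on both strands.
#'
#' `N` enters each strand's cycle with probability `p_enter`; each cycle
#' exits back to `N` with probability `p_exit` per codon, so gene lengths are
#' geometric in whole codons with mean `3 / p_exit` nucleotides. Low
#' `p_enter` and `p_exit` give few, but long, genes.
#'
#' The default emissions give the noncoding state a uniform nucleotide
#' distribution and the coding states modest codon-position-specific biases
#' (about 0.05-0.08 nats of divergence from uniform per position, in the
#' range observed for real coding sequence); reverse-strand emissions are the
#' complement-mirror of the forward ones (`R1` pairs with `C3`, `R3` with
#' `C1`). The initial distribution is the stationary distribution of the
#' transition matrix, reading a sequence as a window cut from a long genome.
#'
#' @param p_enter probability of `N` entering each coding cycle
#'   (`N -> C1` and `N -> R3`); requires `2 * p_enter < 1`.
#' @param p_exit probability of leaving a cycle (`C3 -> N`, `R1 -> N`).
#' @param emissions optional `7 x 4` emission matrix (rows in state order
#'   `N, C1, C2, C3, R1, R2, R3`; columns `A, C, G, T`).
#' @param initial `"stationary"` (default) or `"noncoding"` (start in `N`
#'   with probability 1).
#' @return An [hmm_model()].
#' @examples
#' m <- make_gene_finder()
#' m$transitions["N", ]
#' @export
make_gene_finder <- function(p_enter = 0.004, p_exit = 0.02,
                             emissions = NULL,
                             initial = c("stationary", "noncoding")) {
  initial <- match.arg(initial)
  if (!is.numeric(p_enter) || p_enter < 0 || 2 * p_enter >= 1)
    stop("p_enter must satisfy 0 <= 2 * p_enter < 1", call. = FALSE)
  if (!is.numeric(p_exit) || p_exit < 0 || p_exit > 1)
    stop("p_exit must lie in [0, 1]", call. = FALSE)
  states <- c("N", "C1", "C2", "C3", "R1", "R2", "R3")
  obs <- c("A", "C", "G", "T")
  A <- matrix(0, 7, 7, dimnames = list(states, states))
  A["N", "N"] <- 1 - 2 * p_enter
  A["N", "C1"] <- p_enter
  A["C1", "C2"] <- 1
  A["C2", "C3"] <- 1
  A["C3", "C1"] <- 1 - p_exit
  A["C3", "N"] <- p_exit
  # reverse-strand genes are traversed backwards in sequence order: the
  # entry point (in sequence coordinates) is codon position 3 and the gene
  # start, R1, sits at the right edge, adjacent to the following N
  A["N", "R3"] <- p_enter
  A["R3", "R2"] <- 1
  A["R2", "R1"] <- 1
  A["R1", "R3"] <- 1 - p_exit
  A["R1", "N"] <- p_exit
  if (is.null(emissions)) {
    comp <- function(p) p[c(4, 3, 2, 1)]  # A<->T, C<->G
    c1 <- c(0.30, 0.25, 0.35, 0.10)
    c2 <- c(0.15, 0.40, 0.20, 0.25)
    c3 <- c(0.35, 0.10, 0.25, 0.30)
    emissions <- rbind(N = rep(0.25, 4),
                       C1 = c1, C2 = c2, C3 = c3,
                       R1 = comp(c1), R2 = comp(c2), R3 = comp(c3))
  }
  pi <- if (initial == "noncoding") {
    c(1, 0, 0, 0, 0, 0, 0)
  } else {
    stationary_distribution(A)
  }
  hmm_model(states, obs, pi, A, emissions)
}

# Stationary distribution of a stochastic matrix: solve pi A = pi, sum 1.
stationary_distribution <- function(A) {
  N <- nrow(A)
  M <- rbind(t(A) - diag(N), rep(1, N))
  p <- qr.solve(M, c(rep(0, N), 1))
  p[p < 0 & p > -1e-12] <- 0
  p / sum(p)
}
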