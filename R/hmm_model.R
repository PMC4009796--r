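#' Construct a discrete hidden Markov model
#'
#' An HMM over a finite hidden alphabet of `N` states and a finite observed
#' alphabet of `M` symbols is parameterised by an initial distribution `Pi`
#' (length `N`), a transition matrix `A` (`N x N`, rows sum to one) and an
#' emission matrix `B` (`N x M`, rows sum to one).
#'
#' State and observable names must be non-empty, unique, and contain no
#' whitespace; multi-character names (such as `"C1"`) are allowed throughout.
#'
#' @param hidden_alphabet character vector of hidden-state names.
#' @param observed_alphabet character vector of observable names.
#' @param initial numeric vector `Pi` of initial state probabilities.
#' @param transitions numeric `N x N` matrix `A` of transition probabilities;
#'   `transitions[i, j]` is the probability of moving from state `i` to `j`.
#' @param emissions numeric `N x M` matrix `B`; `emissions[i, m]` is the
#'   probability of state `i` emitting observable `m`.
#'
#' @return An object of class `hmm_model`.
#' @examples
#' m <- hmm_model(c("S", "G"), c("a", "b"),
#'                initial = c(0.6, 0.4),
#'                transitions = matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE),
#'                emissions = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
#' m
#' @export
hmm_model <- function(hidden_alphabet, observed_alphabet, initial,
                      transitions, emissions) {
  hidden_alphabet <- as.character(hidden_alphabet)
  observed_alphabet <- as.character(observed_alphabet)
  transitions <- as.matrix(transitions)
  emissions <- as.matrix(emissions)
  initial <- as.numeric(initial)
  m <- structure(
    list(hidden_alphabet = hidden_alphabet,
         observed_alphabet = observed_alphabet,
         initial = initial,
         transitions = transitions,
         emissions = emissions),
    class = "hmm_model")
  validate_hmm(m)
  dimnames(m$transitions) <- list(hidden_alphabet, hidden_alphabet)
  dimnames(m$emissions) <- list(hidden_alphabet, observed_alphabet)
  names(m$initial) <- hidden_alphabet
  m
}

#' Validate a hidden Markov model object
#'
#' Checks alphabet well-formedness and that `Pi` and each row of `A` and `B`
#' are probability vectors (sums within 1e-9 of one).
#'
#' @param m an `hmm_model`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_hmm <- function(m) {
  stopifnot(inherits(m, "hmm_model"))
  check_names <- function(x, what) {
    if (length(x) < 1L) stop(what, " must be non-empty", call. = FALSE)
    if (anyDuplicated(x)) stop(what, " contains duplicated names", call. = FALSE)
    if (any(!nzchar(x)) || any(grepl("[[:space:]]", x)))
      stop(what, " names must be non-empty and contain no whitespace",
           call. = FALSE)
  }
  check_names(m$hidden_alphabet, "hidden alphabet")
  check_names(m$observed_alphabet, "observed alphabet")
  N <- length(m$hidden_alphabet); M <- length(m$observed_alphabet)
  if (length(m$initial) != N) stop("initial has wrong length", call. = FALSE)
  if (!all(dim(m$transitions) == c(N, N)))
    stop("transition matrix must be N x N", call. = FALSE)
  if (!all(dim(m$emissions) == c(N, M)))
    stop("emission matrix must be N x M", call. = FALSE)
  p <- c(m$initial, m$transitions, m$emissions)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  tol <- 1e-9
  if (abs(sum(m$initial) - 1) > tol)
    stop("initial distribution does not sum to 1", call. = FALSE)
  if (any(abs(rowSums(m$transitions) - 1) > tol))
    stop("transition matrix rows do not sum to 1", call. = FALSE)
  if (any(abs(rowSums(m$emissions) - 1) > tol))
    stop("emission matrix rows do not sum to 1", call. = FALSE)
  invisible(m)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("Hidden Markov model\n")
  cat("  hidden states (", length(x$hidden_alphabet), "): ",
      paste(x$hidden_alphabet, collapse = " "), "\n", sep = "")
  cat("  observables   (", length(x$observed_alphabet), "): ",
      paste(x$observed_alphabet, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Map an observed sequence to 1-based column indices of B, with validation.
obs_index <- function(m, y) {
  y <- as.character(y)
  if (length(y) < 1L) stop("observed sequence must have length >= 1", call. = FALSE)
  idx <- match(y, m$observed_alphabet)
  if (anyNA(idx))
    stop("observed symbol(s) not in the observed alphabet: ",
         paste(unique(y[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

# Map a hidden path to 1-based state indices, with validation.
state_index <- function(m, x) {
  x <- as.character(x)
  if (length(x) < 1L) stop("hidden path must have length >= 1", call. = FALSE)
  idx <- match(x, m$hidden_alphabet)
  if (anyNA(idx))
    stop("hidden state(s) not in the hidden alphabet: ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}
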