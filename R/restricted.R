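#' Count intervals for restricted decoding
#'
#' @param l lower bound (non-negative integer).
#' @param u upper bound (integer, `u >= l`).
#' @return A `count_interval` (integer vector of length 2).
#' @export
count_interval <- function(l, u) {
  if (length(l) != 1L || length(u) != 1L ||
      !is.finite(l) || !is.finite(u) ||
      l != as.integer(l) || u != as.integer(u) || l < 0 || u < l)
    stop("count interval requires integers 0 <= l <= u", call. = FALSE)
  structure(c(l = as.integer(l), u = as.integer(u)), class = "count_interval")
}

as_count_interval <- function(interval) {
  if (inherits(interval, "count_interval")) return(interval)
  if (is.numeric(interval) && length(interval) == 2L)
    return(count_interval(interval[1], interval[2]))
  stop("interval must be a count_interval or a length-2 numeric vector",
       call. = FALSE)
}

aut_check <- function(m, automaton) {
  if (!inherits(automaton, "pattern_automaton"))
    stop("automaton must be a pattern_automaton", call. = FALSE)
  if (!identical(automaton$alphabet, m$hidden_alphabet))
    stop("automaton alphabet does not match the model's hidden alphabet",
         call. = FALSE)
}

acc_logical <- function(automaton) {
  acc <- logical(automaton$n_states)
  acc[automaton$accepting + 1L] <- TRUE
  acc
}

#' The restricted forward algorithm
#'
#' Runs the HMM and the pattern automaton in parallel, filling
#' `alpha_hat_t(h_i, k, q)`: the probability of observing `y_{1:t}`, ending in
#' hidden state `h_i` and automaton state `q`, with exactly `k` pattern
#' occurrences in the hidden prefix. Counts above the cap `K` are truncated
#' (their mass is dropped).
#'
#' The table is scaled with the plain forward algorithm's per-position
#' constants, shared across each whole layer `t`, so summing a layer over
#' `(k, q)` reproduces the scaled plain forward table and the likelihood is
#' exact: `sum_{i,k,q} alpha_hat_T = sum_i alpha_T = P(y) / scaling`.
#'
#' @param m an [hmm_model()].
#' @param y character vector of observables.
#' @param automaton a `pattern_automaton` over the model's hidden alphabet.
#' @param K maximum occurrence count tracked (`K >= 0`).
#' @return A `restricted_table`: list with `table` (array `N x (K+1) x Q x T`
#'   of scaled probabilities, dimensions hidden state, count `0..K`,
#'   automaton state, position), `log_scale`, `log_likelihood` and
#'   `semantics = "alpha_hat"`.
#' @export
restricted_forward <- function(m, y, automaton, K) {
  aut_check(m, automaton)
  yi <- obs_index(m, y)
  stopifnot(length(K) == 1L, K >= 0)
  res <- rf_full_cpp(unname(m$initial), unname(m$transitions),
                     unname(m$emissions), yi, automaton$delta + 1L,
                     acc_logical(automaton), as.integer(K))
  if (!is.finite(res$log_likelihood))
    return(structure(list(table = NULL, log_scale = NULL,
                          log_likelihood = -Inf, semantics = "alpha_hat"),
                     class = "restricted_table"))
  tab <- aperm(res$table, c(3, 2, 1, 4))  # -> (i, k, q, t)
  dimnames(tab) <- list(m$hidden_alphabet, 0:K, NULL, NULL)
  structure(list(table = tab, log_scale = res$log_scale,
                 log_likelihood = res$log_likelihood,
                 semantics = "alpha_hat"),
            class = "restricted_table")
}

#' Posterior distribution of the pattern occurrence count
#'
#' Computes `P(k occurrences of the pattern in the hidden sequence | y)` for
#' `k = 0, 1, 2, ...` using the streaming restricted forward algorithm (two
#' retained time layers, memory independent of `T`). The count cap starts
#' small and is grown geometrically until the accumulated probability mass
#' reaches `mass_threshold` (default 99.99%) or the structural cap implied by
#' the pattern's shortest match length, whichever comes first; the
#' distribution is then truncated at the smallest `k_max` reaching the
#' threshold. The expectation is computed from the truncated vector.
#'
#' @inheritParams restricted_forward
#' @param mass_threshold probability mass at which to truncate
#'   (`0 < mass_threshold <= 1`).
#' @param max_count optional fixed count cap; overrides the adaptive growth
#'   (mass beyond it is reported as `tail_mass`).
#' @return An `occurrence_distribution`: list with `probabilities`
#'   (`p_0 .. p_{k_max}`), `k_max`, `tail_mass`, `expectation`,
#'   `log_likelihood`, and `retained_time_layers` (streaming memory
#'   footprint, always 2).
#' @export
occurrence_distribution <- function(m, y, automaton, mass_threshold = 0.9999,
                                    max_count = NULL) {
  aut_check(m, automaton)
  if (!is.numeric(mass_threshold) || mass_threshold <= 0 || mass_threshold > 1)
    stop("mass_threshold must lie in (0, 1]", call. = FALSE)
  yi <- obs_index(m, y)
  T_ <- length(yi)
  cap <- max_occurrences(automaton, T_)
  run <- function(K) {
    occdist_stream_cpp(unname(m$initial), unname(m$transitions),
                       unname(m$emissions), yi, automaton$delta + 1L,
                       acc_logical(automaton), as.integer(K))
  }
  if (!is.null(max_count)) {
    K <- as.integer(max_count)
    res <- run(K)
    if (!is.finite(res$log_likelihood))
      stop("observed sequence has zero probability under the model",
           call. = FALSE)
  } else {
    K <- min(4L, cap)
    repeat {
      res <- run(K)
      if (!is.finite(res$log_likelihood))
        stop("observed sequence has zero probability under the model",
             call. = FALSE)
      if (sum(res$pk) >= mass_threshold || K >= cap) break
      K <- min(2L * K, cap)
    }
  }
  pk <- res$pk
  cum <- cumsum(pk)
  k_max <- if (any(cum >= mass_threshold)) which(cum >= mass_threshold)[1] - 1L
           else length(pk) - 1L
  p <- pk[seq_len(k_max + 1L)]
  names(p) <- 0:k_max
  structure(list(probabilities = p,
                 k_max = k_max,
                 tail_mass = max(0, 1 - sum(p)),
                 expectation = sum((0:k_max) * p),
                 log_likelihood = res$log_likelihood,
                 mass_threshold = mass_threshold,
                 retained_time_layers = res$retained_time_layers,
                 mode = automaton$mode),
            class = "occurrence_distribution")
}

#' @export
print.occurrence_distribution <- function(x, ...) {
  cat("occurrence-count distribution (", x$mode, " matching)\n", sep = "")
  cat("  k_max:", x$k_max, " tail mass:", format(x$tail_mass, digits = 4),
      "\n")
  cat("  expectation:", format(x$expectation, digits = 6),
      " log-likelihood:", format(x$log_likelihood, digits = 8), "\n")
  print(round(x$probabilities, 6))
  invisible(x)
}

#' Choose a count interval from an occurrence distribution
#'
#' The default policy sets `l = u =` the expectation rounded half away from
#' zero. The `"central"` policy returns the smallest interval of counts whose
#' posterior mass is at least `level` around the distribution's quantiles.
#'
#' @param dist an [occurrence_distribution()].
#' @param policy `"expectation"` or `"central"`.
#' @param level coverage for the central interval.
#' @return A [count_interval()].
#' @export
interval_from_distribution <- function(dist,
                                       policy = c("expectation", "central"),
                                       level = 0.95) {
  policy <- match.arg(policy)
  if (policy == "expectation") {
    k <- as.integer(floor(dist$expectation + 0.5))
    count_interval(k, k)
  } else {
    cum <- cumsum(dist$probabilities)
    lo <- (1 - level) / 2
    l <- which(cum >= lo)[1] - 1L
    u <- which(cum >= 1 - lo)[1]
    if (is.na(u)) u <- dist$k_max
    else u <- u - 1L
    count_interval(l, max(l, u))
  }
}

#' Restricted Viterbi decoding
#'
#' Finds a hidden path maximising the joint probability `P(y, x)` subject to
#' the number of pattern occurrences `O_r(x)` lying in `[l, u]`. The dynamic
#' program runs in log space over the product of hidden states, occurrence
#' counts `0..u` and automaton states; backtracking starts from the best
#' table entry at `T` with `k` in `[l, u]` (ties broken towards the lowest
#' count, then lowest hidden-state index, then lowest automaton state).
#'
#' @inheritParams restricted_forward
#' @param interval a [count_interval()] or length-2 numeric `c(l, u)`.
#' @return An `hmm_decoding` with `score = log P(y, x*)`, the realised
#'   `count` (verified independently with [count_occurrences()]) and the
#'   requested `interval`.
#' @export
restricted_viterbi <- function(m, y, automaton, interval) {
  aut_check(m, automaton)
  interval <- as_count_interval(interval)
  yi <- obs_index(m, y)
  res <- rviterbi_cpp(log(unname(m$initial)), log(unname(m$transitions)),
                      log(unname(m$emissions)), yi, automaton$delta + 1L,
                      acc_logical(automaton), interval[1], interval[2])
  finish_restricted(res, m, automaton, interval, "restricted_viterbi")
}

#' Restricted posterior-Viterbi decoding
#'
#' Maximises `prod_t gamma_t(x_t)` over syntactically correct paths whose
#' pattern occurrence count lies in `[l, u]`. The posterior `gamma` is taken
#' from the unrestricted forward-backward pass; the restriction applies only
#' to the path search (no renormalisation within the constrained set).
#'
#' @inheritParams restricted_viterbi
#' @return An `hmm_decoding` with `score = sum_t log gamma_t(x*_t)`.
#' @export
restricted_posterior_viterbi <- function(m, y, automaton, interval) {
  aut_check(m, automaton)
  interval <- as_count_interval(interval)
  po <- hmm_posterior(m, y)
  mask <- ifelse(unname(m$transitions) > 0, 0, -Inf)
  init_mask <- ifelse(unname(m$initial) > 0, 0, -Inf)
  res <- rpv_cpp(log(unname(po$gamma)), mask, init_mask,
                 automaton$delta + 1L, acc_logical(automaton),
                 interval[1], interval[2])
  finish_restricted(res, m, automaton, interval, "restricted_posterior_viterbi")
}

finish_restricted <- function(res, m, automaton, interval, decoder) {
  if (!is.finite(res$score)) {
    feas <- which(is.finite(res$feasible)) - 1L
    stop("no decoding with a pattern occurrence count in [", interval[1],
         ", ", interval[2], "]; feasible counts up to the cap: ",
         if (length(feas)) paste(feas, collapse = ", ") else "(none)",
         call. = FALSE)
  }
  path <- m$hidden_alphabet[res$path]
  realised <- count_occurrences(automaton, path)
  if (realised != res$k)
    stop("internal error: backtracked occurrence count disagrees with the ",
         "automaton recount")
  new_decoding(path, res$score, decoder = decoder, count = realised,
               interval = as.integer(interval))
}
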