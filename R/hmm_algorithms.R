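#' Joint log-probability of an observed sequence and a hidden path
#'
#' Computes `log P(y, x) = log[ Pi[x1] B[x1,y1] prod_t A[x_{t-1},x_t] B[x_t,y_t] ]`.
#' Returns `-Inf` when any factor is zero.
#'
#' @param m an [hmm_model()].
#' @param y character vector of observables.
#' @param x character vector of hidden states, same length as `y`.
#' @return The joint log-probability (scalar; `-Inf` allowed).
#' @export
hmm_joint_log_prob <- function(m, y, x) {
  yi <- obs_index(m, y)
  xi <- state_index(m, x)
  if (length(yi) != length(xi))
    stop("observed sequence and hidden path must have equal length", call. = FALSE)
  T_ <- length(yi)
  lp <- log(m$initial[xi[1]]) + log(m$emissions[xi[1], yi[1]])
  if (T_ > 1) {
    tr <- m$transitions[cbind(xi[-T_], xi[-1])]
    em <- m$emissions[cbind(xi[-1], yi[-1])]
    lp <- lp + sum(log(tr)) + sum(log(em))
  }
  if (is.nan(lp)) lp <- -Inf
  unname(lp)
}

#' The forward algorithm (scaled)
#'
#' Fills the forward table `alpha_t(h_i) = P(y_{1:t}, X_t = h_i)` with
#' per-position scaling: row `t` of the returned `alpha` is normalised to sum
#' to one and the scaling constants are recorded, so
#' `alpha_t(h_i) = alpha[t, i] * exp(cumsum(log_scale)[t])`.
#'
#' @param m an [hmm_model()].
#' @param y character vector of observables.
#' @return A list with `alpha` (`T x N`, scaled), `log_scale` (length `T`)
#'   and `log_likelihood` (`log P(y)`, `-Inf` if the sequence has zero
#'   probability).
#' @export
hmm_forward <- function(m, y) {
  yi <- obs_index(m, y)
  T_ <- length(yi); N <- length(m$hidden_alphabet)
  alpha <- matrix(0, T_, N, dimnames = list(NULL, m$hidden_alphabet))
  log_scale <- rep(-Inf, T_)
  a <- m$initial * m$emissions[, yi[1]]
  for (t in seq_len(T_)) {
    if (t > 1) a <- as.numeric(a %*% m$transitions) * m$emissions[, yi[t]]
    ct <- sum(a)
    if (ct == 0) {  # zero-probability observation: likelihood is exactly 0
      return(list(alpha = alpha, log_scale = log_scale, log_likelihood = -Inf))
    }
    a <- a / ct
    alpha[t, ] <- a
    log_scale[t] <- log(ct)
  }
  list(alpha = alpha, log_scale = log_scale, log_likelihood = sum(log_scale))
}

#' The backward algorithm (scaled)
#'
#' Fills the backward table `beta_t(h_i) = P(y_{t+1:T} | X_t = h_i)` using the
#' forward pass's scaling constants: `beta[T, ] = 1` and
#' `beta_t(h_i) = beta[t, i] * exp(sum(log_scale[(t+1):T]))`.
#'
#' @inheritParams hmm_forward
#' @return A list with `beta` (`T x N`, scaled) and `log_scale` (the forward
#'   scaling constants).
#' @export
hmm_backward <- function(m, y) {
  yi <- obs_index(m, y)
  fw <- hmm_forward(m, y)
  if (!is.finite(fw$log_likelihood))
    stop("observed sequence has zero probability under the model", call. = FALSE)
  T_ <- length(yi); N <- length(m$hidden_alphabet)
  beta <- matrix(0, T_, N, dimnames = list(NULL, m$hidden_alphabet))
  beta[T_, ] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      v <- m$emissions[, yi[t + 1]] * beta[t + 1, ]
      beta[t, ] <- as.numeric(m$transitions %*% v) / exp(fw$log_scale[t + 1])
    }
  }
  list(beta = beta, log_scale = fw$log_scale)
}

#' The Viterbi algorithm
#'
#' Finds a hidden path maximising the joint probability `P(y, x)`, in log
#' space. Ties in every argmax (including backtracking) are broken towards
#' the lowest hidden-state index, so the result is deterministic.
#'
#' @inheritParams hmm_forward
#' @return An `hmm_decoding`: list with `path` (character), `score`
#'   (`max_x log P(y, x)`), `count` (`NA` here; filled by pattern-aware
#'   decoders), `decoder` and `interval`.
#' @export
hmm_viterbi <- function(m, y) {
  yi <- obs_index(m, y)
  T_ <- length(yi); N <- length(m$hidden_alphabet)
  logA <- log(m$transitions); logB <- log(m$emissions)
  V <- log(m$initial) + logB[, yi[1]]
  ptr <- matrix(0L, T_, N)
  if (T_ > 1) {
    for (t in 2:T_) {
      S <- V + logA                      # S[j, i] = V[j] + log a_{j,i}
      best <- apply(S, 2, max)
      ptr[t, ] <- apply(S, 2, which.max) # first max = lowest state index
      V <- best + logB[, yi[t]]
    }
  }
  if (max(V) == -Inf)
    stop("no valid decoding: every hidden path has probability 0", call. = FALSE)
  path <- integer(T_)
  path[T_] <- which.max(V)
  if (T_ > 1) for (t in T_:2) path[t - 1] <- ptr[t, path[t]]
  new_decoding(m$hidden_alphabet[path], unname(max(V)), decoder = "viterbi")
}

#' Posterior state probabilities
#'
#' Computes `gamma_t(h_i) = P(X_t = h_i | y) = alpha_t(h_i) beta_t(h_i) / P(y)`
#' via the scaled forward and backward passes. Rows sum to one.
#'
#' @inheritParams hmm_forward
#' @return A list with `gamma` (`T x N`) and `log_likelihood`.
#' @export
hmm_posterior <- function(m, y) {
  fw <- hmm_forward(m, y)
  if (!is.finite(fw$log_likelihood))
    stop("observed sequence has zero probability under the model", call. = FALSE)
  bw <- hmm_backward(m, y)
  g <- fw$alpha * bw$beta
  g <- g / rowSums(g)
  list(gamma = g, log_likelihood = fw$log_likelihood)
}

#' Posterior decoding
#'
#' Per-position argmax of the posterior, `x_t = argmax_i gamma_t(h_i)` (ties
#' to the lowest state index). The result maximises the expected number of
#' correctly decoded positions but may be syntactically invalid: it can use
#' transitions whose probability is zero under the model.
#'
#' @inheritParams hmm_forward
#' @return Character vector of hidden-state names.
#' @export
hmm_posterior_decode <- function(m, y) {
  po <- hmm_posterior(m, y)
  m$hidden_alphabet[apply(po$gamma, 1, which.max)]
}

#' The posterior-Viterbi algorithm
#'
#' Maximises `prod_t gamma_t(x_t)` over syntactically correct paths, i.e.
#' paths whose start has positive initial probability and whose consecutive
#' transitions all satisfy `a_{x_{t-1}, x_t} > 0`. When the plain posterior
#' decoding happens to be syntactically correct, this returns the same path.
#'
#' @inheritParams hmm_forward
#' @return An `hmm_decoding` with `score = max sum_t log gamma_t(x_t)`.
#' @export
hmm_posterior_viterbi <- function(m, y) {
  po <- hmm_posterior(m, y)
  lg <- log(po$gamma)
  T_ <- nrow(lg); N <- ncol(lg)
  mask <- ifelse(m$transitions > 0, 0, -Inf)  # allowed transitions only
  D <- lg[1, ] + ifelse(m$initial > 0, 0, -Inf)
  ptr <- matrix(0L, T_, N)
  if (T_ > 1) {
    for (t in 2:T_) {
      S <- D + mask
      best <- apply(S, 2, max)
      ptr[t, ] <- apply(S, 2, which.max)
      D <- best + lg[t, ]
    }
  }
  if (max(D) == -Inf)
    stop("no syntactically correct decoding exists", call. = FALSE)
  path <- integer(T_)
  path[T_] <- which.max(D)
  if (T_ > 1) for (t in T_:2) path[t - 1] <- ptr[t, path[t]]
  new_decoding(m$hidden_alphabet[path], unname(max(D)),
               decoder = "posterior_viterbi")
}

#' Sample an observed/hidden sequence pair
#'
#' Draws `(y, x)` from the joint distribution of the model. A single R
#' pseudo-random stream is used; pass `seed` for a self-contained reproducible
#' draw, or leave it `NULL` to consume the caller's RNG stream (as the
#' simulation drivers do). Categories are drawn by inverse-CDF over the
#' stored alphabet order.
#'
#' @param m an [hmm_model()].
#' @param length sequence length `T >= 1`.
#' @param seed optional integer seed.
#' @return List with `observed` and `hidden` character vectors.
#' @export
hmm_sample <- function(m, length, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  T_ <- as.integer(length)
  N <- base::length(m$hidden_alphabet)
  cumA <- t(apply(m$transitions, 1, cumsum))
  cumB <- t(apply(m$emissions, 1, cumsum))
  cumPi <- cumsum(m$initial)
  u <- runif(2L * T_)
  x <- integer(T_); y <- integer(T_)
  x[1] <- sum(u[1] > cumPi) + 1L
  y[1] <- sum(u[2] > cumB[x[1], ]) + 1L
  if (T_ > 1) for (t in 2:T_) {
    x[t] <- sum(u[2 * t - 1] > cumA[x[t - 1], ]) + 1L
    y[t] <- sum(u[2 * t] > cumB[x[t], ]) + 1L
  }
  list(observed = m$observed_alphabet[y], hidden = m$hidden_alphabet[x])
}

new_decoding <- function(path, score, decoder, count = NA_integer_,
                         interval = NULL) {
  structure(list(path = path, score = score, count = count,
                 decoder = decoder, interval = interval),
            class = "hmm_decoding")
}

#' @export
print.hmm_decoding <- function(x, ...) {
  cat("HMM decoding (", x$decoder, ")\n", sep = "")
  cat("  length:", length(x$path), " score (log):", format(x$score), "\n")
  if (!is.na(x$count)) cat("  pattern occurrences:", x$count, "\n")
  if (!is.null(x$interval))
    cat("  requested interval: [", x$interval[1], ", ", x$interval[2], "]\n",
        sep = "")
  cat("  path: ", paste(head(x$path, 15), collapse = " "),
      if (length(x$path) > 15) " ..." else "", "\n", sep = "")
  invisible(x)
}
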