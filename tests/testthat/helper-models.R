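# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (path enumeration, regex suffix tests) so it cannot
# share bugs with the dynamic programs it checks.

two_state_model <- function() {
  hmm_model(c("S", "G"), c("a", "b"),
            initial = c(0.6, 0.4),
            transitions = matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE),
            emissions = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
}

# Random dense model; optionally knock out `zeros` transition entries.
rand_model <- function(N, M, zeros = 0) {
  repeat {
    A <- matrix(runif(N * N), N)
    if (zeros > 0) A[sample(N * N, zeros)] <- 0
    if (any(rowSums(A) == 0)) next
    A <- A / rowSums(A)
    B <- matrix(runif(N * M), N)
    B <- B / rowSums(B)
    pi <- runif(N); pi <- pi / sum(pi)
    return(hmm_model(paste0("s", seq_len(N)),
                     letters[seq_len(M)], pi, A, B))
  }
}

rand_obs <- function(m, T_) sample(m$observed_alphabet, T_, replace = TRUE)

# All hidden paths of length T_ as a matrix of state indices (rows = paths).
all_paths <- function(N, T_) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(N)), T_)))
}

# log P(y, x) computed by a naive term-by-term loop.
naive_joint <- function(m, y, xi) {
  yi <- match(y, m$observed_alphabet)
  p <- m$initial[xi[1]] * m$emissions[xi[1], yi[1]]
  if (length(yi) > 1) for (t in 2:length(yi)) {
    p <- p * m$transitions[xi[t - 1], xi[t]] * m$emissions[xi[t], yi[t]]
  }
  unname(p)
}

enum_likelihood <- function(m, y) {
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  sum(apply(paths, 1, function(xi) naive_joint(m, y, xi)))
}

enum_viterbi_score <- function(m, y) {
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  log(max(apply(paths, 1, function(xi) naive_joint(m, y, xi))))
}

enum_gamma <- function(m, y) {
  N <- length(m$hidden_alphabet); T_ <- length(y)
  paths <- all_paths(N, T_)
  w <- apply(paths, 1, function(xi) naive_joint(m, y, xi))
  g <- matrix(0, T_, N)
  for (t in seq_len(T_)) for (i in seq_len(N)) {
    g[t, i] <- sum(w[paths[, t] == i])
  }
  g / sum(w)
}

# Is a path syntactically correct (positive start and transition probs)?
path_valid <- function(m, xi) {
  if (m$initial[xi[1]] == 0) return(FALSE)
  T_ <- length(xi)
  if (T_ == 1) return(TRUE)
  all(m$transitions[cbind(xi[-T_], xi[-1])] > 0)
}

enum_pv_score <- function(m, y) {
  g <- enum_gamma(m, y)
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    xi <- paths[r, ]
    if (!path_valid(m, xi)) next
    s <- sum(log(g[cbind(seq_along(xi), xi)]))
    if (s > best) best <- s
  }
  best
}
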