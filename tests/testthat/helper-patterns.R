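# Regex-based occurrence oracles, independent of the automaton machinery.
# Test alphabets here use single-character state names so that a pattern
# string maps directly onto an R regular expression by dropping whitespace.

pattern_to_regex <- function(src) gsub("[[:space:]]+", "", src)

# Overlapping count: positions t such that some suffix of x_{1:t} is in L(r).
oracle_count_overlapping <- function(src, x) {
  rx <- paste0("(", pattern_to_regex(src), ")$")
  s <- vapply(seq_along(x), function(t) paste(x[1:t], collapse = ""), "")
  sum(grepl(rx, s, perl = TRUE))
}

# Non-overlapping count: scan left to right, restart after each match.
oracle_count_non_overlapping <- function(src, x) {
  rx <- paste0("^(?:", pattern_to_regex(src), ")$")
  count <- 0L; s <- 1L
  for (t in seq_along(x)) {
    for (j in s:t) {
      if (grepl(rx, paste(x[j:t], collapse = ""), perl = TRUE)) {
        count <- count + 1L
        s <- t + 1L
        break
      }
    }
  }
  count
}

oracle_count <- function(src, x, mode) {
  if (mode == "overlapping") oracle_count_overlapping(src, x)
  else oracle_count_non_overlapping(src, x)
}

# Full occurrence-count distribution by path enumeration.
enum_count_distribution <- function(m, y, src, mode) {
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  w <- apply(paths, 1, function(xi) naive_joint(m, y, xi))
  ks <- apply(paths, 1, function(xi)
    oracle_count(src, m$hidden_alphabet[xi], mode))
  p <- tapply(w, factor(ks, levels = 0:length(y)), sum, default = 0)
  as.numeric(p / sum(w))
}

# Best constrained joint score over enumerated paths.
enum_restricted_viterbi_score <- function(m, y, src, mode, l, u) {
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    xi <- paths[r, ]
    k <- oracle_count(src, m$hidden_alphabet[xi], mode)
    if (k < l || k > u) next
    s <- log(naive_joint(m, y, xi))
    if (s > best) best <- s
  }
  best
}

enum_restricted_pv_score <- function(m, y, src, mode, l, u) {
  g <- enum_gamma(m, y)
  paths <- all_paths(length(m$hidden_alphabet), length(y))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    xi <- paths[r, ]
    if (!path_valid(m, xi)) next
    k <- oracle_count(src, m$hidden_alphabet[xi], mode)
    if (k < l || k > u) next
    s <- sum(log(g[cbind(seq_along(xi), xi)]))
    if (s > best) best <- s
  }
  best
}

# Small pool of patterns over a two-state {A, B} hidden alphabet; all have
# automata with at most 5 states.
ab_pattern_pool <- c("A", "B B", "A B", "(A B)|(B A)", "A B? A", "A+ B",
                     "(A|B) A")

ab_model <- function(zeros = 0) {
  m <- rand_model(2, 2, zeros)
  m$hidden_alphabet <- c("A", "B")
  names(m$initial) <- c("A", "B")
  dimnames(m$transitions) <- list(c("A", "B"), c("A", "B"))
  rownames(m$emissions) <- c("A", "B")
  m
}
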