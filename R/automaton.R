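#' Build the suffix-matching automaton for a pattern
#'
#' Constructs the minimal complete deterministic finite automaton (DFA)
#' recognising `(h1 | ... | hN)* r`, i.e. all strings over the hidden
#' alphabet having the pattern `r` as a suffix. While a hidden path is
#' consumed, every entry into an accepting state marks one (overlapping)
#' occurrence of the pattern ending at that position.
#'
#' The construction goes syntax tree -> Thompson NFA (with a self-loop over
#' the full alphabet on the start state) -> subset construction -> Moore
#' partition-refinement minimisation -> breadth-first canonical renumbering
#' from the initial state using the declared alphabet order, so the automaton
#' is reproducible byte-for-byte. State ids are 0-based; the initial state is
#' always 0.
#'
#' @param r a [parse_pattern()] result.
#' @return A `pattern_automaton` with fields `n_states`, `initial` (always
#'   `0`), `accepting` (0-based ids), `delta` (`Q x N` integer matrix of
#'   0-based target states, columns in alphabet order), `alphabet`, `mode`
#'   (`"overlapping"`), `pattern` and `shortest_match`.
#' @examples
#' hid <- c("N", "C1", "C2", "C3", "R1", "R2", "R3")
#' fa <- build_fa(parse_pattern("(N C1)|(R1 N)", hid))
#' fa
#' @export
build_fa <- function(r) {
  stopifnot(inherits(r, "pattern_expr"))
  dfa <- build_dfa(r, suffix = TRUE)
  dfa <- minimize_dfa(dfa)
  dfa <- renumber_bfs(dfa)
  if ((dfa$initial - 1L) %in% dfa$accepting)
    stop("internal error: initial state accepting although the pattern ",
         "cannot match the empty string")
  structure(
    list(n_states = dfa$n, initial = 0L,
         accepting = dfa$accepting,
         delta = dfa$delta,          # 0-based targets, Q x N
         alphabet = r$alphabet,
         mode = "overlapping",
         pattern = r$source,
         shortest_match = shortest_match_length(r)),
    class = "pattern_automaton")
}

#' Convert an overlapping-match automaton to non-overlapping matching
#'
#' Redirects every transition out of an accepting state to the corresponding
#' transition of the initial state: the automaton restarts after each match,
#' so matches cannot overlap. States, initial state and accepting set are
#' kept identical and the result is deliberately not re-minimised, preserving
#' state identities of the overlapping automaton. The operation is idempotent.
#'
#' @param fa a `pattern_automaton`.
#' @return A `pattern_automaton` with `mode = "non_overlapping"`.
#' @export
extend_to_ea <- function(fa) {
  stopifnot(inherits(fa, "pattern_automaton"))
  if (!length(fa$accepting))
    stop("automaton has no accepting states", call. = FALSE)
  delta <- fa$delta
  delta[fa$accepting + 1L, ] <- delta[rep(fa$initial + 1L, length(fa$accepting)), ]
  fa$delta <- delta
  fa$mode <- "non_overlapping"
  fa
}

#' Count pattern occurrences in a hidden path
#'
#' Runs the automaton over the path from its initial state and counts how
#' many times an accepting state is entered. With an overlapping automaton
#' ([build_fa()]) this is the number of positions at which some suffix of the
#' consumed prefix matches the pattern; with a non-overlapping automaton
#' ([extend_to_ea()]) matches are counted left to right without overlap.
#'
#' @param automaton a `pattern_automaton`.
#' @param x character vector of hidden-state names.
#' @return Non-negative integer count.
#' @export
count_occurrences <- function(automaton, x) {
  xi <- match(as.character(x), automaton$alphabet)
  if (anyNA(xi))
    stop("hidden state(s) not in the automaton alphabet: ",
         paste(unique(x[is.na(xi)]), collapse = ", "), call. = FALSE)
  acc <- logical(automaton$n_states)
  acc[automaton$accepting + 1L] <- TRUE
  count_occ_cpp(automaton$delta + 1L, acc, as.integer(xi),
                automaton$initial + 1L)
}

#' Length of the shortest string the pattern matches
#'
#' Breadth-first search on the DFA of the pattern's own language (no suffix
#' closure). Used to cap the maximum number of occurrences in a path of
#' length `T`: `T - L_min + 1` for overlapping and `floor(T / L_min)` for
#' non-overlapping matching.
#'
#' @param r a [parse_pattern()] result.
#' @return Positive integer.
#' @export
shortest_match_length <- function(r) {
  stopifnot(inherits(r, "pattern_expr"))
  dfa <- build_dfa(r, suffix = FALSE)
  dist <- rep(NA_integer_, dfa$n)
  dist[dfa$initial] <- 0L
  queue <- dfa$initial
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    if ((q - 1L) %in% dfa$accepting) return(dist[q])
    for (s in seq_len(ncol(dfa$delta))) {
      nxt <- dfa$delta[q, s] + 1L
      if (is.na(dist[nxt])) {
        dist[nxt] <- dist[q] + 1L
        queue <- c(queue, nxt)
      }
    }
  }
  stop("pattern matches no string (empty language)", call. = FALSE)
}

#' Maximum number of pattern occurrences in a path of given length
#'
#' @param automaton a `pattern_automaton`.
#' @param T_ path length.
#' @return Integer structural cap on the occurrence count.
#' @export
max_occurrences <- function(automaton, T_) {
  L <- automaton$shortest_match
  if (automaton$mode == "overlapping") max(0L, as.integer(T_ - L + 1L))
  else as.integer(floor(T_ / L))
}

#' Inverse transition sets of an automaton
#'
#' For each target state `q` and symbol `h`, the set of source states
#' `{q' : delta(q', h) = q}`. For every fixed symbol these sets partition the
#' state set.
#'
#' @param automaton a `pattern_automaton`.
#' @return A list indexed by symbol name; each element is a list of integer
#'   vectors of 0-based source states, one per target state.
#' @export
inverse_transitions <- function(automaton) {
  Q <- automaton$n_states
  out <- lapply(seq_along(automaton$alphabet), function(s) {
    lapply(seq_len(Q) - 1L, function(q)
      which(automaton$delta[, s] == q) - 1L)
  })
  names(out) <- automaton$alphabet
  out
}

#' @export
print.pattern_automaton <- function(x, ...) {
  cat("pattern automaton (", x$mode, ") for: ", x$pattern, "\n", sep = "")
  cat("  states: ", x$n_states, "  initial: ", x$initial,
      "  accepting: {", paste(x$accepting, collapse = ", "), "}\n", sep = "")
  cat("  alphabet: ", paste(x$alphabet, collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---- internal construction -------------------------------------------------

# Thompson construction. Fragments are (start, accept); transitions collected
# in the builder environment. suffix = TRUE adds a full-alphabet self-loop on
# the NFA start state, yielding the language Sigma* L(r).
build_dfa <- function(r, suffix) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$sym_from <- integer(0); env$sym_lab <- integer(0); env$sym_to <- integer(0)
  env$eps_from <- integer(0); env$eps_to <- integer(0)
  new_state <- function() { env$n <- env$n + 1L; env$n }
  add_sym <- function(from, lab, to) {
    env$sym_from <- c(env$sym_from, from)
    env$sym_lab <- c(env$sym_lab, lab)
    env$sym_to <- c(env$sym_to, to)
  }
  add_eps <- function(from, to) {
    env$eps_from <- c(env$eps_from, from)
    env$eps_to <- c(env$eps_to, to)
  }
  alphabet <- r$alphabet
  frag <- function(node) {
    switch(node$op,
      sym = {
        s <- new_state(); a <- new_state()
        add_sym(s, match(node$name, alphabet), a)
        c(s, a)
      },
      cat = {
        fr <- lapply(node$args, frag)
        for (i in seq_len(length(fr) - 1L)) add_eps(fr[[i]][2], fr[[i + 1]][1])
        c(fr[[1]][1], fr[[length(fr)]][2])
      },
      alt = {
        s <- new_state(); a <- new_state()
        for (f in lapply(node$args, frag)) {
          add_eps(s, f[1]); add_eps(f[2], a)
        }
        c(s, a)
      },
      star = {
        s <- new_state(); a <- new_state()
        f <- frag(node$arg)
        add_eps(s, f[1]); add_eps(f[2], a); add_eps(s, a); add_eps(f[2], f[1])
        c(s, a)
      },
      plus = {
        f <- frag(node$arg)
        add_eps(f[2], f[1])
        f
      },
      opt = {
        s <- new_state(); a <- new_state()
        f <- frag(node$arg)
        add_eps(s, f[1]); add_eps(f[2], a); add_eps(s, a)
        c(s, a)
      })
  }
  f <- frag(r$ast)
  start <- f[1]; accept <- f[2]
  if (suffix) for (s in seq_along(alphabet)) add_sym(start, s, start)

  n <- env$n
  eps_adj <- split(env$eps_to, factor(env$eps_from, levels = seq_len(n)))
  closure <- function(states) {
    seen <- logical(n); seen[states] <- TRUE
    stack <- states
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (t in eps_adj[[q]]) if (!seen[t]) { seen[t] <- TRUE; stack <- c(stack, t) }
    }
    which(seen)
  }
  # subset construction
  key <- function(s) if (length(s)) paste(s, collapse = ",") else "empty"
  start_set <- closure(start)
  subsets <- list(start_set)
  index <- new.env(parent = emptyenv())
  assign(key(start_set), 1L, envir = index)
  delta <- matrix(NA_integer_, nrow = 0, ncol = length(alphabet))
  i <- 1L
  while (i <= length(subsets)) {
    cur <- subsets[[i]]
    row <- integer(length(alphabet))
    for (s in seq_along(alphabet)) {
      targets <- env$sym_to[env$sym_lab == s & env$sym_from %in% cur]
      nxt <- if (length(targets)) closure(unique(targets)) else integer(0)
      k <- key(nxt)
      id <- if (exists(k, envir = index, inherits = FALSE))
        get(k, envir = index) else NULL
      if (is.null(id)) {
        subsets[[length(subsets) + 1L]] <- nxt
        id <- length(subsets)
        assign(k, id, envir = index)
      }
      row[s] <- id - 1L  # 0-based
    }
    delta <- rbind(delta, row)
    i <- i + 1L
  }
  accepting <- which(vapply(subsets, function(s) accept %in% s, logical(1))) - 1L
  list(n = length(subsets), initial = 1L, delta = unname(delta),
       accepting = accepting, alphabet = alphabet)
}

# Moore partition refinement; keeps the automaton complete.
minimize_dfa <- function(dfa) {
  n <- dfa$n
  acc <- logical(n); acc[dfa$accepting + 1L] <- TRUE
  block <- as.integer(acc) + 1L
  repeat {
    sig <- apply(cbind(block, matrix(block[dfa$delta + 1L], nrow = n)), 1,
                 paste, collapse = "|")
    new_block <- as.integer(factor(sig, levels = unique(sig)))
    if (identical(new_block, block)) break
    block <- new_block
  }
  nb <- max(block)
  reps <- match(seq_len(nb), block)  # representative state per block
  delta <- matrix(block[dfa$delta[reps, , drop = FALSE] + 1L] - 1L,
                  nrow = nb)
  list(n = nb, initial = block[dfa$initial],
       delta = delta,
       accepting = sort(unique(block[dfa$accepting + 1L])) - 1L,
       alphabet = dfa$alphabet)
}

# BFS renumbering from the initial state using alphabet column order; the
# initial state becomes 0. Unreachable states (none should exist) dropped.
renumber_bfs <- function(dfa) {
  n <- dfa$n
  order_new <- rep(NA_integer_, n)
  order_new[dfa$initial] <- 1L
  queue <- dfa$initial; nxt_id <- 1L
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    for (s in seq_len(ncol(dfa$delta))) {
      t <- dfa$delta[q, s] + 1L
      if (is.na(order_new[t])) {
        nxt_id <- nxt_id + 1L
        order_new[t] <- nxt_id
        queue <- c(queue, t)
      }
    }
  }
  keep <- which(!is.na(order_new))
  perm <- order(order_new[keep])      # old ids in new order
  old_in_new <- keep[perm]
  new_of_old <- rep(NA_integer_, n)
  new_of_old[old_in_new] <- seq_along(old_in_new)
  delta <- matrix(new_of_old[dfa$delta[old_in_new, , drop = FALSE] + 1L] - 1L,
                  nrow = length(old_in_new))
  list(n = length(old_in_new), initial = 1L, delta = unname(delta),
       accepting = sort(new_of_old[dfa$accepting + 1L]) - 1L,
       alphabet = dfa$alphabet)
}

## ---- serialisation ---------------------------------------------------------

#' Write / read an automaton as plain text, or export DOT
#'
#' The text format lists the state count, alphabet, initial state, accepting
#' states, mode, pattern source and one `from symbol to` transition per line.
#' `automaton_dot` renders the automaton in Graphviz DOT for visualisation.
#'
#' @param automaton a `pattern_automaton`.
#' @param path file path.
#' @return `read_automaton` returns a `pattern_automaton`; `automaton_dot`
#'   returns a character scalar of DOT source.
#' @export
write_automaton <- function(automaton, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("states", automaton$n_states),
    paste("alphabet", paste(automaton$alphabet, collapse = " ")),
    paste("initial", automaton$initial),
    paste("accepting", paste(automaton$accepting, collapse = " ")),
    paste("mode", automaton$mode),
    paste("pattern", automaton$pattern),
    paste("shortest_match", automaton$shortest_match),
    "transitions"), con)
  for (q in seq_len(automaton$n_states)) {
    for (s in seq_along(automaton$alphabet)) {
      writeLines(paste(q - 1L, automaton$alphabet[s], automaton$delta[q, s]),
                 con)
    }
  }
  invisible(path)
}

#' @rdname write_automaton
#' @export
read_automaton <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- function(k) {
    l <- grep(paste0("^", k, "( |$)"), lines, value = TRUE)[1]
    sub(paste0("^", k, " ?"), "", l)
  }
  n <- as.integer(kv("states"))
  alphabet <- strsplit(kv("alphabet"), " ")[[1]]
  acc_str <- kv("accepting")
  tr_at <- which(lines == "transitions")[1]
  tr <- do.call(rbind, strsplit(lines[(tr_at + 1L):length(lines)], " "))
  delta <- matrix(NA_integer_, n, length(alphabet))
  delta[cbind(as.integer(tr[, 1]) + 1L, match(tr[, 2], alphabet))] <-
    as.integer(tr[, 3])
  if (anyNA(delta)) stop("automaton file has an incomplete transition table",
                         call. = FALSE)
  structure(
    list(n_states = n, initial = as.integer(kv("initial")),
         accepting = if (nzchar(acc_str))
           as.integer(strsplit(acc_str, " ")[[1]]) else integer(0),
         delta = delta, alphabet = alphabet, mode = kv("mode"),
         pattern = kv("pattern"),
         shortest_match = as.integer(kv("shortest_match"))),
    class = "pattern_automaton")
}

#' @rdname write_automaton
#' @export
automaton_dot <- function(automaton) {
  lines <- c("digraph automaton {", "  rankdir=LR;",
             "  node [shape=circle];",
             paste0("  ", automaton$accepting, " [shape=doublecircle];"),
             "  __start [shape=point];",
             paste0("  __start -> ", automaton$initial, ";"))
  for (q in seq_len(automaton$n_states)) {
    for (s in seq_along(automaton$alphabet)) {
      lines <- c(lines, paste0("  ", q - 1L, " -> ", automaton$delta[q, s],
                               " [label=\"", automaton$alphabet[s], "\"];"))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
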