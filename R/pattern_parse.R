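#' Parse a regular expression over hidden-state names
#'
#' Patterns are regular expressions whose atoms are hidden-state names.
#' Because state names may have several characters (`"C1"`, `"R1"`), atoms
#' must be separated by whitespace or by operator characters: the gene-start
#' pattern is written `"(N C1)|(R1 N)"`. Supported operators are alternation
#' `|`, concatenation (juxtaposition), grouping `()`, Kleene star `*`, plus
#' `+` and option `?`.
#'
#' Patterns whose language contains the empty string are rejected: an empty
#' match would make "number of occurrences" ill-defined (every position of
#' every path would match).
#'
#' @param text the pattern string.
#' @param alphabet character vector of hidden-state names the leaves are
#'   validated against.
#' @return A `pattern_expr`: list with `source`, `ast` and `alphabet`.
#' @examples
#' parse_pattern("(N C1)|(R1 N)", c("N", "C1", "C2", "C3", "R1", "R2", "R3"))
#' @export
parse_pattern <- function(text, alphabet) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("pattern must be a non-empty string", call. = FALSE)
  toks <- tokenize_pattern(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  ast <- parse_alt(st)
  if (st$pos <= length(st$toks))
    stop("parse error: unexpected '", st$toks[[st$pos]]$value,
         "' in pattern", call. = FALSE)
  leaves <- collect_leaves(ast)
  unknown <- setdiff(leaves, alphabet)
  if (length(unknown))
    stop("unknown hidden-state name(s) in pattern: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nullable_node(ast))
    stop("pattern matches the empty string; occurrence counting requires a ",
         "non-empty match", call. = FALSE)
  structure(list(source = text, ast = ast, alphabet = as.character(alphabet)),
            class = "pattern_expr")
}

#' @export
print.pattern_expr <- function(x, ...) {
  cat("pattern expression: ", x$source, "\n", sep = "")
  cat("  alphabet: ", paste(x$alphabet, collapse = " "), "\n", sep = "")
  invisible(x)
}

tokenize_pattern <- function(text) {
  chars <- strsplit(text, "")[[1]]
  ops <- c("(", ")", "|", "*", "+", "?")
  toks <- list(); buf <- character(0)
  flush <- function() {
    if (length(buf))
      toks[[length(toks) + 1L]] <<- list(type = "name",
                                         value = paste(buf, collapse = ""))
    buf <<- character(0)
  }
  for (ch in chars) {
    if (grepl("[[:space:]]", ch)) flush()
    else if (ch %in% ops) { flush(); toks[[length(toks) + 1L]] <- list(type = ch, value = ch) }
    else buf <- c(buf, ch)
  }
  flush()
  if (!length(toks)) stop("pattern must be a non-empty string", call. = FALSE)
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]]$type else ""

parse_alt <- function(st) {
  branches <- list(parse_cat(st))
  while (peek(st) == "|") {
    st$pos <- st$pos + 1L
    branches[[length(branches) + 1L]] <- parse_cat(st)
  }
  if (length(branches) == 1L) branches[[1]] else list(op = "alt", args = branches)
}

parse_cat <- function(st) {
  parts <- list()
  repeat {
    tk <- peek(st)
    if (tk %in% c("name", "(")) parts[[length(parts) + 1L]] <- parse_rep(st)
    else break
  }
  if (!length(parts))
    stop("parse error: expected a state name or '(' in pattern", call. = FALSE)
  if (length(parts) == 1L) parts[[1]] else list(op = "cat", args = parts)
}

parse_rep <- function(st) {
  node <- parse_atom(st)
  repeat {
    tk <- peek(st)
    if (tk == "*") { node <- list(op = "star", arg = node); st$pos <- st$pos + 1L }
    else if (tk == "+") { node <- list(op = "plus", arg = node); st$pos <- st$pos + 1L }
    else if (tk == "?") { node <- list(op = "opt", arg = node); st$pos <- st$pos + 1L }
    else break
  }
  node
}

parse_atom <- function(st) {
  tk <- peek(st)
  if (tk == "name") {
    v <- st$toks[[st$pos]]$value
    st$pos <- st$pos + 1L
    list(op = "sym", name = v)
  } else if (tk == "(") {
    st$pos <- st$pos + 1L
    node <- parse_alt(st)
    if (peek(st) != ")")
      stop("parse error: unbalanced parentheses in pattern", call. = FALSE)
    st$pos <- st$pos + 1L
    node
  } else {
    stop("parse error: expected a state name or '(' in pattern", call. = FALSE)
  }
}

collect_leaves <- function(node) {
  switch(node$op,
         sym = node$name,
         alt = ,
         cat = unique(unlist(lapply(node$args, collect_leaves))),
         star = ,
         plus = ,
         opt = collect_leaves(node$arg))
}

nullable_node <- function(node) {
  switch(node$op,
         sym = FALSE,
         alt = any(vapply(node$args, nullable_node, logical(1))),
         cat = all(vapply(node$args, nullable_node, logical(1))),
         star = TRUE,
         opt = TRUE,
         plus = nullable_node(node$arg))
}
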