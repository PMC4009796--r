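#' Read and write HMM specifications
#'
#' The on-disk format is a YAML mapping with keys `hidden_alphabet`,
#' `observed_alphabet`, `initial`, `transitions` and `emissions`.
#' `transitions` and `emissions` are lists of rows (one row per hidden state,
#' in alphabet order) of decimal floats.
#'
#' @param path file path.
#' @return `read_hmm` returns an [hmm_model()]; `write_hmm` returns `path`
#'   invisibly.
#' @examples
#' f <- system.file("extdata", "example_hmm.yaml", package = "patternHMM")
#' read_hmm(f)
#' @export
read_hmm <- function(path) {
  spec <- yaml::read_yaml(path)
  need <- c("hidden_alphabet", "observed_alphabet", "initial",
            "transitions", "emissions")
  miss <- setdiff(need, names(spec))
  if (length(miss))
    stop("HMM file is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  hmm_model(
    hidden_alphabet = as.character(spec$hidden_alphabet),
    observed_alphabet = as.character(spec$observed_alphabet),
    initial = as.numeric(spec$initial),
    transitions = do.call(rbind, lapply(spec$transitions, as.numeric)),
    emissions = do.call(rbind, lapply(spec$emissions, as.numeric)))
}

#' @rdname read_hmm
#' @param m an `hmm_model`.
#' @export
write_hmm <- function(m, path) {
  validate_hmm(m)
  spec <- list(
    hidden_alphabet = m$hidden_alphabet,
    observed_alphabet = m$observed_alphabet,
    initial = as.numeric(m$initial),
    transitions = lapply(seq_len(nrow(m$transitions)),
                         function(i) as.numeric(m$transitions[i, ])),
    emissions = lapply(seq_len(nrow(m$emissions)),
                       function(i) as.numeric(m$emissions[i, ])))
  yaml::write_yaml(spec, path, precision = 15L)
  invisible(path)
}

#' Read observed sequences
#'
#' Two formats are supported: FASTA, for observed alphabets whose symbols are
#' single characters (each residue is one symbol), and token-per-line plain
#' text (one sequence per line, symbols separated by whitespace) for
#' multi-character observables.
#'
#' @param path file path.
#' @param format `"auto"` (FASTA if the first non-blank line starts with
#'   `>`), `"fasta"`, or `"tokens"`.
#' @return A named list of character vectors, one per sequence.
#' @export
read_observed <- function(path, format = c("auto", "fasta", "tokens")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- ""
    lines <- readLines(path, warn = FALSE)
    nb <- lines[nzchar(trimws(lines))]
    if (length(nb)) first <- substr(trimws(nb[[1]]), 1, 1)
    format <- if (identical(first, ">")) "fasta" else "tokens"
  }
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                               forceDNAtolower = FALSE, set.attributes = FALSE)
    lapply(seqs, as.character)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
    names(out) <- paste0("seq", seq_along(out))
    out
  }
}

#' Read and write hidden paths
#'
#' Hidden paths are stored as whitespace-separated state names, one sequence
#' per line (state names such as `"C1"` are multi-character, so FASTA is not
#' suitable).
#'
#' @param path file path.
#' @return `read_paths` returns a list of character vectors.
#' @export
read_paths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
}

#' @rdname read_paths
#' @param paths a character vector (single path) or list of character vectors.
#' @export
write_paths <- function(paths, path) {
  if (is.character(paths)) paths <- list(paths)
  writeLines(vapply(paths, paste, "", collapse = " "), path)
  invisible(path)
}
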