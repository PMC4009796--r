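#' Label schemes: mapping hidden states to gene classes
#'
#' A label scheme is a total mapping from each hidden-state name to one of
#' `"forward_gene"`, `"reverse_gene"` or `"noncoding"`, used to binarise
#' hidden paths for strand-wise evaluation.
#'
#' @param mapping named character vector; names are hidden states, values the
#'   three class labels.
#' @return A `label_scheme`.
#' @export
label_scheme <- function(mapping) {
  classes <- c("forward_gene", "reverse_gene", "noncoding")
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("mapping must be a named character vector", call. = FALSE)
  bad <- setdiff(unique(mapping), classes)
  if (length(bad))
    stop("unknown label class(es): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(classes, collapse = ", "), call. = FALSE)
  structure(mapping, class = "label_scheme")
}

#' Default scheme for the seven-state gene-finder model
#' @return A [label_scheme()] mapping `C1..C3` to `forward_gene`, `R1..R3`
#'   to `reverse_gene` and `N` to `noncoding`.
#' @export
gene_finder_scheme <- function() {
  label_scheme(c(N = "noncoding",
                 C1 = "forward_gene", C2 = "forward_gene", C3 = "forward_gene",
                 R1 = "reverse_gene", R2 = "reverse_gene", R3 = "reverse_gene"))
}

#' Binarise a hidden path for one strand
#'
#' Positions whose state belongs to the selected strand's gene class become
#' 1; everything else (including genes on the other strand) becomes 0.
#'
#' @param path character vector of hidden-state names.
#' @param scheme a [label_scheme()]; must cover every state in `path`.
#' @param strand `"forward"` or `"reverse"`.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_path <- function(path, scheme, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  cls <- unclass(scheme)[as.character(path)]
  if (anyNA(cls))
    stop("state(s) not covered by the label scheme: ",
         paste(unique(path[is.na(cls)]), collapse = ", "), call. = FALSE)
  target <- if (strand == "forward") "forward_gene" else "reverse_gene"
  as.integer(cls == target)
}

#' Nucleotide-level prediction quality
#'
#' Position-by-position comparison of binary labels. Sensitivity is
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)` and MCC the Matthews
#' correlation coefficient
#' `(tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#'
#' Degenerate denominators: a ratio with an empty denominator class is
#' reported as 1 (its error count is necessarily 0); an MCC with a zero
#' denominator is reported as 0. Both situations are listed in `degenerate`.
#'
#' @param truth,pred integer 0/1 vectors of equal length.
#' @return List with `counts` (`tp`, `tn`, `fp`, `fn`), `metrics`
#'   (`sensitivity`, `specificity`, `mcc`) and `degenerate` (character).
#' @export
nucleotide_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and prediction must have equal length", call. = FALSE)
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L)))
    stop("labels must be binary (0/1)", call. = FALSE)
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  degenerate <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "sensitivity"); 1
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    degenerate <- c(degenerate, "specificity"); 1
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  else {
    degenerate <- c(degenerate, "mcc"); 0
  }
  list(counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
       metrics = list(sensitivity = sens, specificity = spec, mcc = mcc),
       degenerate = degenerate)
}

#' Extract gene intervals from binary labels
#'
#' Maximal runs of 1s as 0-based half-open intervals `[start, end)`.
#'
#' @param labels integer 0/1 vector.
#' @return Data frame with columns `start` and `end`, in order.
#' @export
extract_genes <- function(labels) {
  if (!length(labels))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Gene-level prediction quality (50% overlap rule)
#'
#' A predicted gene counts as one true positive if it covers at least 50% of
#' the length of some true gene, and as one false positive otherwise. A true
#' gene with no single prediction covering at least 50% of it is one false
#' negative - except true genes that are cumulatively covered more than 50%
#' by several predictions, which are disregarded. True negatives are not
#' defined at the gene level. Recall is `tp / (tp + fn)`, precision
#' `tp / (tp + fp)` and the F-score their harmonic mean,
#' `2 tp / (2 tp + fn + fp)`.
#'
#' A single prediction covering two true genes still counts as one true
#' positive, and both true genes count as found.
#'
#' @param truth_genes,pred_genes data frames with 0-based half-open `start`,
#'   `end` columns (as from [extract_genes()]); intervals within one set must
#'   not overlap.
#' @return List with `counts` (`tp`, `fp`, `fn`, `found`, `disregarded`),
#'   `metrics` (`recall`, `precision`, `f_score`) and `degenerate`.
#' @export
gene_metrics <- function(truth_genes, pred_genes) {
  check_intervals <- function(g, what) {
    if (!nrow(g)) return(invisible())
    if (any(g$end <= g$start))
      stop(what, ": intervals must satisfy start < end", call. = FALSE)
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop(what, ": intervals overlap within one list", call. = FALSE)
  }
  check_intervals(truth_genes, "truth")
  check_intervals(pred_genes, "prediction")
  nt <- nrow(truth_genes); np <- nrow(pred_genes)
  ov <- matrix(0, nrow = np, ncol = nt)
  if (np && nt) {
    for (p in seq_len(np)) for (g in seq_len(nt)) {
      ov[p, g] <- max(0, min(pred_genes$end[p], truth_genes$end[g]) -
                         max(pred_genes$start[p], truth_genes$start[g]))
    }
  }
  tlen <- truth_genes$end - truth_genes$start
  single <- if (np && nt)
    sweep(ov, 2, 0.5 * tlen, ">=") else matrix(FALSE, np, nt)
  tp <- if (np) sum(apply(single, 1, any)) else 0L
  fp <- np - tp
  found <- if (nt) apply(single, 2, any) else logical(0)
  cum_cover <- if (nt) colSums(ov) else numeric(0)
  disregarded <- !found & cum_cover > 0.5 * tlen
  fn <- sum(!found & !disregarded)
  degenerate <- character(0)
  rec <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 1
  }
  f <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else {
    degenerate <- c(degenerate, "f_score"); 1
  }
  list(counts = list(tp = tp, fp = fp, fn = fn,
                     found = sum(found), disregarded = sum(disregarded)),
       metrics = list(recall = rec, precision = prec, f_score = f),
       degenerate = degenerate)
}

#' Evaluate a decoding against a true hidden path
#'
#' Binarises truth and prediction twice - once treating reverse-strand genes
#' as noncoding and evaluating the forward strand, once vice versa - computes
#' nucleotide- and gene-level measures for each strand, and returns the
#' arithmetic mean of the two strands' metrics (averaging happens at the
#' metric level, not the confusion-count level).
#'
#' @param truth,pred character vectors of hidden-state names, equal length.
#' @param scheme a [label_scheme()].
#' @return List with `nucleotide` (`sensitivity`, `specificity`, `mcc`),
#'   `gene` (`recall`, `precision`, `f_score`) and `per_strand` detail.
#' @export
evaluate_pair <- function(truth, pred, scheme) {
  if (length(truth) != length(pred))
    stop("truth and prediction must have equal length", call. = FALSE)
  one_strand <- function(strand) {
    bt <- binarize_path(truth, scheme, strand)
    bp <- binarize_path(pred, scheme, strand)
    nm <- nucleotide_metrics(bt, bp)
    gm <- gene_metrics(extract_genes(bt), extract_genes(bp))
    list(nucleotide = nm, gene = gm)
  }
  fw <- one_strand("forward")
  rv <- one_strand("reverse")
  nuc <- list(
    sensitivity = (fw$nucleotide$metrics$sensitivity +
                   rv$nucleotide$metrics$sensitivity) / 2,
    specificity = (fw$nucleotide$metrics$specificity +
                   rv$nucleotide$metrics$specificity) / 2,
    mcc = (fw$nucleotide$metrics$mcc + rv$nucleotide$metrics$mcc) / 2)
  gene <- list(
    recall = (fw$gene$metrics$recall + rv$gene$metrics$recall) / 2,
    precision = (fw$gene$metrics$precision + rv$gene$metrics$precision) / 2,
    f_score = (fw$gene$metrics$f_score + rv$gene$metrics$f_score) / 2)
  list(nucleotide = nuc, gene = gene,
       per_strand = list(forward = fw, reverse = rv))
}
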