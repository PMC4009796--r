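#' Configuration for the simulation experiments
#'
#' Defines the simulation grid: for each sequence length, `replicates`
#' observed/hidden pairs are drawn from `model`, and the pattern occurrence
#' count in the hidden truth is compared with estimates derived from the
#' observed sequence alone. The defaults reproduce the full study grid
#' (lengths 500 to 1500 in steps of 25, 500 replicates per length); pass
#' smaller values for quick runs.
#'
#' @param lengths integer vector of sequence lengths.
#' @param replicates replicates per length.
#' @param seed integer seed for the whole experiment.
#' @param pattern pattern string over the model's hidden alphabet.
#' @param overlap `"overlapping"` or `"non_overlapping"` matching.
#' @param mass_threshold truncation threshold for
#'   [occurrence_distribution()].
#' @param interval_policy policy for deriving the restricted decoders'
#'   count interval from the distribution (see
#'   [interval_from_distribution()]).
#' @param model the [hmm_model()] to simulate from.
#' @param scheme [label_scheme()] used by the quality experiment.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(lengths = seq(500L, 1500L, by = 25L),
                              replicates = 500L,
                              seed = 1L,
                              pattern = "(N C1)|(R1 N)",
                              overlap = c("overlapping", "non_overlapping"),
                              mass_threshold = 0.9999,
                              interval_policy = c("expectation", "central"),
                              model = make_gene_finder(),
                              scheme = gene_finder_scheme()) {
  overlap <- match.arg(overlap)
  interval_policy <- match.arg(interval_policy)
  expr <- parse_pattern(pattern, model$hidden_alphabet)
  if (any(lengths < shortest_match_length(expr)))
    stop("every length must be at least the pattern's shortest match length",
         call. = FALSE)
  stopifnot(all(lengths >= 1), replicates >= 1)
  structure(list(lengths = as.integer(lengths),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), pattern = pattern,
                 overlap = overlap, mass_threshold = mass_threshold,
                 interval_policy = interval_policy,
                 model = model, scheme = scheme),
            class = "experiment_config")
}

config_automaton <- function(config) {
  fa <- build_fa(parse_pattern(config$pattern, config$model$hidden_alphabet))
  if (config$overlap == "non_overlapping") extend_to_ea(fa) else fa
}

#' Occurrence-count recovery experiment
#'
#' For each replicate, draws a sequence pair, records the true occurrence
#' count of the pattern in the hidden truth, and three estimates computed
#' from the observed sequence alone: the expectation of the posterior
#' occurrence distribution, and the counts realised by the Viterbi and
#' posterior-Viterbi decodings. Per length and estimator, the summary gives
#' the median and 0.025/0.975 quantiles of the normalised difference
#' `estimate / true - 1`. Replicates with a true count of zero (for which
#' the normalised difference is undefined) are excluded from the quantiles
#' and counted separately.
#'
#' @param config an [experiment_config()].
#' @return List with `records` (one row per replicate), `summary` (one row
#'   per length and estimator) and `config`. Deterministic given the config
#'   seed.
#' @export
run_count_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  aut <- config_automaton(config)
  m <- config$model
  rec <- vector("list", length(config$lengths) * config$replicates)
  idx <- 0L
  for (L in config$lengths) {
    for (rep_i in seq_len(config$replicates)) {
      pair <- hmm_sample(m, L)
      true_k <- count_occurrences(aut, pair$hidden)
      dist <- occurrence_distribution(m, pair$observed, aut,
                                      config$mass_threshold)
      vit <- hmm_viterbi(m, pair$observed)
      pv <- hmm_posterior_viterbi(m, pair$observed)
      idx <- idx + 1L
      rec[[idx]] <- data.frame(
        length = L, replicate = rep_i, true_count = true_k,
        expectation = dist$expectation,
        viterbi_count = count_occurrences(aut, vit$path),
        posterior_viterbi_count = count_occurrences(aut, pv$path))
    }
  }
  records <- do.call(rbind, rec)
  estimators <- c("expectation", "viterbi_count", "posterior_viterbi_count")
  summ <- list()
  for (L in config$lengths) {
    sub <- records[records$length == L, ]
    nz <- sub[sub$true_count > 0, ]
    for (est in estimators) {
      nd <- nz[[est]] / nz$true_count - 1
      summ[[length(summ) + 1L]] <- data.frame(
        length = L, estimator = est,
        median = median(nd),
        q025 = unname(quantile(nd, 0.025)),
        q975 = unname(quantile(nd, 0.975)),
        n = nrow(nz), n_zero_true = nrow(sub) - nrow(nz))
    }
  }
  list(records = records, summary = do.call(rbind, summ), config = config)
}

#' Decoding-quality experiment
#'
#' For each replicate, decodes the observed sequence with the Viterbi,
#' posterior-Viterbi, restricted Viterbi and restricted posterior-Viterbi
#' algorithms (the restricted ones with the count interval derived from the
#' occurrence distribution under the configured policy), evaluates each
#' decoding against the hidden truth with [evaluate_pair()], and averages
#' the metrics per length and decoder. Replicates whose count interval is
#' infeasible for a restricted decoder are skipped for that decoder and
#' counted in `n_skipped`.
#'
#' @param config an [experiment_config()].
#' @return List with `records` (one row per replicate and decoder),
#'   `summary` (means per length and decoder), `n_skipped` and `config`.
#' @export
run_quality_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  aut <- config_automaton(config)
  m <- config$model
  rec <- list()
  n_skipped <- 0L
  for (L in config$lengths) {
    for (rep_i in seq_len(config$replicates)) {
      pair <- hmm_sample(m, L)
      dist <- occurrence_distribution(m, pair$observed, aut,
                                      config$mass_threshold)
      interval <- interval_from_distribution(dist, config$interval_policy)
      decoders <- list(
        viterbi = function() hmm_viterbi(m, pair$observed),
        posterior_viterbi = function() hmm_posterior_viterbi(m, pair$observed),
        restricted_viterbi = function()
          restricted_viterbi(m, pair$observed, aut, interval),
        restricted_posterior_viterbi = function()
          restricted_posterior_viterbi(m, pair$observed, aut, interval))
      for (dn in names(decoders)) {
        dec <- tryCatch(decoders[[dn]](), error = function(e) NULL)
        if (is.null(dec)) { n_skipped <- n_skipped + 1L; next }
        ev <- evaluate_pair(pair$hidden, dec$path, config$scheme)
        rec[[length(rec) + 1L]] <- data.frame(
          length = L, replicate = rep_i, decoder = dn,
          sensitivity = ev$nucleotide$sensitivity,
          specificity = ev$nucleotide$specificity,
          mcc = ev$nucleotide$mcc,
          recall = ev$gene$recall,
          precision = ev$gene$precision,
          f_score = ev$gene$f_score,
          count = count_occurrences(aut, dec$path),
          interval_l = interval[1], interval_u = interval[2])
      }
    }
  }
  records <- do.call(rbind, rec)
  metrics <- c("sensitivity", "specificity", "mcc",
               "recall", "precision", "f_score")
  summ <- list()
  for (L in unique(records$length)) {
    for (dn in unique(records$decoder)) {
      sub <- records[records$length == L & records$decoder == dn, ]
      row <- as.data.frame(as.list(colMeans(sub[metrics])))
      row$length <- L; row$decoder <- dn; row$n <- nrow(sub)
      summ[[length(summ) + 1L]] <- row[c("length", "decoder", metrics, "n")]
    }
  }
  list(records = records, summary = do.call(rbind, summ),
       n_skipped = n_skipped, config = config)
}
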