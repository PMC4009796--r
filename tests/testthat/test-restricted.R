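# Restricted forward, occurrence distribution, and the two restricted
# decoders, checked against closed forms and exhaustive path enumeration.

g_automaton <- function(mode = "overlapping") {
  fa <- build_fa(parse_pattern("G", c("S", "G")))
  if (mode == "non_overlapping") extend_to_ea(fa) else fa
}

test_that("restricted forward reproduces the two-path closed form at T = 1", {
  m <- two_state_model()
  fg <- g_automaton()
  rf <- restricted_forward(m, "a", fg, K = 1)
  unscaled <- rf$table[, , , 1] * exp(rf$log_scale[1])
  expect_equal(sum(unscaled["S", "0", ]), 0.54)
  expect_equal(sum(unscaled["G", "1", ]), 0.08)
  expect_equal(sum(unscaled[, "1", ]), 0.08)
  expect_equal(rf$log_likelihood, log(0.62))
})

test_that("restricted forward layers marginalise to the plain forward table", {
  set.seed(707)
  for (rep in 1:6) {
    m <- ab_model(zeros = sample(0:1, 1))
    src <- sample(ab_pattern_pool, 1)
    fa <- build_fa(parse_pattern(src, c("A", "B")))
    y <- rand_obs(m, 12)
    if (!is.finite(hmm_forward(m, y)$log_likelihood)) next
    rf <- restricted_forward(m, y, fa, K = 12)
    fw <- hmm_forward(m, y)
    expect_equal(rf$log_scale, fw$log_scale, tolerance = 1e-12)
    for (t in c(1, 5, 12)) {
      marg <- apply(rf$table[, , , t, drop = FALSE], 1, sum)
      expect_equal(unname(marg), unname(fw$alpha[t, ]), tolerance = 1e-9)
    }
    # no path of length t can contain more than t occurrences
    for (t in 1:4) {
      above <- rf$table[, (t + 2):13, , t]
      expect_true(all(above == 0))
    }
  }
})

test_that("occurrence distribution matches the closed form and enumeration", {
  m <- two_state_model()
  fg <- g_automaton()
  d <- occurrence_distribution(m, "a", fg)
  expect_equal(unname(d$probabilities), c(0.54, 0.08) / 0.62)
  expect_equal(d$expectation, 0.08 / 0.62)

  set.seed(808)
  for (rep in 1:6) {
    m2 <- ab_model()
    src <- sample(ab_pattern_pool, 1)
    fa <- build_fa(parse_pattern(src, c("A", "B")))
    mode <- sample(c("overlapping", "non_overlapping"), 1)
    aut <- if (mode == "overlapping") fa else extend_to_ea(fa)
    T_ <- sample(3:6, 1)
    y <- rand_obs(m2, T_)
    d2 <- occurrence_distribution(m2, y, aut, mass_threshold = 1)
    ref <- enum_count_distribution(m2, y, src, mode)
    got <- rep(0, T_ + 1)
    got[seq_along(d2$probabilities)] <- d2$probabilities
    expect_lt(sum(abs(got - ref)) / 2, 1e-9)  # total variation
    expect_equal(sum(d2$probabilities) + d2$tail_mass, 1, tolerance = 1e-9)
  }
})

test_that("an unreachable pattern concentrates the distribution at zero", {
  m <- hmm_model(c("S", "G"), c("a", "b"), c(1, 0),
                 matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE),
                 matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  d <- occurrence_distribution(m, c("a", "a", "a"), g_automaton())
  expect_equal(unname(d$probabilities), c(1, 0, 0)[seq_along(d$probabilities)])
  expect_equal(d$expectation, 0)
})

test_that("truncation threshold bounds the tail and is respected", {
  m <- make_gene_finder()
  aut <- build_fa(parse_pattern("(N C1)|(R1 N)", m$hidden_alphabet))
  set.seed(12)
  y <- hmm_sample(m, 400)$observed
  d <- occurrence_distribution(m, y, aut, mass_threshold = 0.9999)
  expect_gte(sum(d$probabilities), 0.9999)
  expect_lt(d$tail_mass, 1e-4)
  full <- occurrence_distribution(m, y, aut, mass_threshold = 1)
  expect_equal(sum(full$probabilities), 1, tolerance = 1e-9)
  # truncated expectation close to the full one
  expect_lt(abs(full$expectation - d$expectation), 1e-2)
})

test_that("restricted Viterbi matches the constrained enumeration oracle", {
  set.seed(909)
  for (rep in 1:8) {
    m <- ab_model(zeros = sample(0:1, 1))
    src <- sample(ab_pattern_pool, 1)
    mode <- sample(c("overlapping", "non_overlapping"), 1)
    fa <- build_fa(parse_pattern(src, c("A", "B")))
    aut <- if (mode == "overlapping") fa else extend_to_ea(fa)
    T_ <- sample(3:6, 1)
    y <- rand_obs(m, T_)
    if (!is.finite(hmm_forward(m, y)$log_likelihood)) next
    for (interval in list(c(0, T_), c(1, 1), c(0, 0), c(1, 2))) {
      ref <- enum_restricted_viterbi_score(m, y, src, mode,
                                           interval[1], interval[2])
      if (!is.finite(ref)) {
        expect_error(restricted_viterbi(m, y, aut, interval), "no decoding")
      } else {
        dec <- restricted_viterbi(m, y, aut, interval)
        expect_equal(dec$score, ref, tolerance = 1e-9)
        expect_gte(dec$count, interval[1])
        expect_lte(dec$count, interval[2])
        expect_equal(hmm_joint_log_prob(m, y, dec$path), dec$score,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("forcing one occurrence when the optimum has none lowers the score", {
  m <- two_state_model()
  # strongly S-favouring observation: unrestricted optimum stays in S
  y <- rep("a", 5)
  fg <- g_automaton()
  v <- hmm_viterbi(m, y)
  expect_equal(count_occurrences(fg, v$path), 0L)
  r <- restricted_viterbi(m, y, fg, c(1, 1))
  expect_equal(r$count, 1L)
  expect_lt(r$score, v$score)
})

test_that("restricted posterior-Viterbi matches its enumeration oracle", {
  set.seed(1010)
  for (rep in 1:8) {
    m <- ab_model(zeros = sample(0:1, 1))
    src <- sample(ab_pattern_pool, 1)
    mode <- sample(c("overlapping", "non_overlapping"), 1)
    fa <- build_fa(parse_pattern(src, c("A", "B")))
    aut <- if (mode == "overlapping") fa else extend_to_ea(fa)
    T_ <- sample(3:5, 1)
    y <- rand_obs(m, T_)
    if (!is.finite(hmm_forward(m, y)$log_likelihood)) next
    for (interval in list(c(0, T_), c(1, 1))) {
      ref <- enum_restricted_pv_score(m, y, src, mode,
                                      interval[1], interval[2])
      if (!is.finite(ref)) {
        expect_error(restricted_posterior_viterbi(m, y, aut, interval),
                     "no decoding")
      } else {
        dec <- restricted_posterior_viterbi(m, y, aut, interval)
        expect_equal(dec$score, ref, tolerance = 1e-9)
        xi <- match(dec$path, m$hidden_alphabet)
        expect_true(path_valid(m, xi))
        expect_gte(dec$count, interval[1])
        expect_lte(dec$count, interval[2])
      }
    }
  }
})

test_that("a forced all-match decoding on a one-state model scores zero", {
  one <- hmm_model("N", c("a", "b"), 1, matrix(1), matrix(c(0.5, 0.5), 1))
  aut <- build_fa(parse_pattern("N", "N"))
  T_ <- 4
  dec <- restricted_posterior_viterbi(one, rep("a", T_), aut, c(T_, T_))
  expect_equal(dec$path, rep("N", T_))
  expect_equal(dec$score, 0)
})

test_that("infeasible intervals raise an informative error", {
  m <- two_state_model()
  fg <- g_automaton()
  err <- tryCatch(restricted_viterbi(m, c("a", "a"), fg, c(5, 7)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "no decoding with a pattern occurrence count in \\[5, 7\\]")
  expect_match(err, "feasible")
  expect_error(count_interval(-1, 2), "0 <= l <= u")
  expect_error(count_interval(3, 2), "0 <= l <= u")
})

test_that("interval selection policies follow the distribution", {
  m <- two_state_model()
  d <- occurrence_distribution(m, c("a", "b", "b"), g_automaton(),
                               mass_threshold = 1)
  iv <- interval_from_distribution(d, "expectation")
  expect_equal(unname(iv["l"]), unname(iv["u"]))
  expect_equal(unname(iv["l"]), floor(d$expectation + 0.5))
  civ <- interval_from_distribution(d, "central", level = 0.95)
  expect_lte(civ["l"], civ["u"])
  mass <- sum(d$probabilities[(civ["l"]:civ["u"]) + 1])
  expect_gte(mass, 0.9)
})
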