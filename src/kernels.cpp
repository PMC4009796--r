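#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Count entries into accepting states while consuming x (1-based indices).
// [[Rcpp::export]]
int count_occ_cpp(IntegerMatrix delta, LogicalVector acc, IntegerVector xidx,
                  int q0) {
  int q = q0 - 1, count = 0;
  for (int t = 0; t < xidx.size(); ++t) {
    q = delta(q, xidx[t] - 1) - 1;
    if (acc[q]) ++count;
  }
  return count;
}

// Restricted forward, full table. The table is normalised with the plain
// forward algorithm's per-position scaling constants (shared across the
// whole (i, k, q) layer at each t), so layer sums reproduce the scaled plain
// forward table exactly and the entries at T are P(X_T=i, K=k, Q_T=q | y).
// Mass escaping beyond the count cap K is dropped (truncation).
// [[Rcpp::export]]
List rf_full_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                 IntegerVector yidx, IntegerMatrix delta, LogicalVector acc,
                 int K) {
  const int N = pi.size(), Q = delta.nrow(), T = yidx.size(), K1 = K + 1;
  const int layer = N * K1 * Q;
  std::vector<double> rprev(layer, 0.0), rnew(layer, 0.0);
  std::vector<double> aprev(N), anew(N);
  NumericVector table(static_cast<R_xlen_t>(layer) * T);
  NumericVector log_scale(T);
  auto id = [&](int i, int k, int q) { return (i * K1 + k) * Q + q; };

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    int y = yidx[t] - 1;
    std::fill(rnew.begin(), rnew.end(), 0.0);
    if (t == 0) {
      for (int i = 0; i < N; ++i) {
        double a = pi[i] * B(i, y);
        anew[i] = a;
        if (a > 0.0) {
          int q = delta(0, i) - 1;  // row 0 is the initial state
          int k = acc[q] ? 1 : 0;
          if (k <= K) rnew[id(i, k, q)] += a;
        }
      }
    } else {
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += aprev[j] * A(j, i);
        anew[i] = s * B(i, y);
      }
      for (int j = 0; j < N; ++j) {
        for (int qp = 0; qp < Q; ++qp) {
          for (int k = 0; k <= K; ++k) {
            double v = rprev[id(j, k, qp)];
            if (v == 0.0) continue;
            for (int i = 0; i < N; ++i) {
              double a = A(j, i);
              if (a == 0.0) continue;
              double b = B(i, y);
              if (b == 0.0) continue;
              int qn = delta(qp, i) - 1;
              int kn = k + (acc[qn] ? 1 : 0);
              if (kn <= K) rnew[id(i, kn, qn)] += v * a * b;
            }
          }
        }
      }
    }
    double c = 0.0;
    for (int i = 0; i < N; ++i) c += anew[i];
    if (c == 0.0)
      return List::create(_["log_likelihood"] = NEG_INF);
    for (int i = 0; i < N; ++i) aprev[i] = anew[i] / c;
    for (int u = 0; u < layer; ++u) {
      rprev[u] = rnew[u] / c;
      table[static_cast<R_xlen_t>(t) * layer + u] = rprev[u];
    }
    log_scale[t] = std::log(c);
    loglik += log_scale[t];
  }
  table.attr("dim") = IntegerVector::create(Q, K1, N, T);
  return List::create(_["table"] = table, _["log_scale"] = log_scale,
                      _["log_likelihood"] = loglik);
}

// Streaming occurrence-count distribution: identical recursion but only two
// time layers are retained, so memory is independent of T.
// [[Rcpp::export]]
List occdist_stream_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                        IntegerVector yidx, IntegerMatrix delta,
                        LogicalVector acc, int K) {
  const int N = pi.size(), Q = delta.nrow(), T = yidx.size(), K1 = K + 1;
  const int layer = N * K1 * Q;
  std::vector<double> rprev(layer, 0.0), rnew(layer, 0.0);
  std::vector<double> aprev(N), anew(N);
  auto id = [&](int i, int k, int q) { return (i * K1 + k) * Q + q; };

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    int y = yidx[t] - 1;
    std::fill(rnew.begin(), rnew.end(), 0.0);
    if (t == 0) {
      for (int i = 0; i < N; ++i) {
        double a = pi[i] * B(i, y);
        anew[i] = a;
        if (a > 0.0) {
          int q = delta(0, i) - 1;
          int k = acc[q] ? 1 : 0;
          if (k <= K) rnew[id(i, k, q)] += a;
        }
      }
    } else {
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += aprev[j] * A(j, i);
        anew[i] = s * B(i, y);
      }
      for (int j = 0; j < N; ++j) {
        for (int qp = 0; qp < Q; ++qp) {
          for (int k = 0; k <= K; ++k) {
            double v = rprev[id(j, k, qp)];
            if (v == 0.0) continue;
            for (int i = 0; i < N; ++i) {
              double a = A(j, i);
              if (a == 0.0) continue;
              double b = B(i, y);
              if (b == 0.0) continue;
              int qn = delta(qp, i) - 1;
              int kn = k + (acc[qn] ? 1 : 0);
              if (kn <= K) rnew[id(i, kn, qn)] += v * a * b;
            }
          }
        }
      }
    }
    double c = 0.0;
    for (int i = 0; i < N; ++i) c += anew[i];
    if (c == 0.0)
      return List::create(_["log_likelihood"] = NEG_INF);
    for (int i = 0; i < N; ++i) aprev[i] = anew[i] / c;
    for (int u = 0; u < layer; ++u) rprev[u] = rnew[u] / c;
    loglik += std::log(c);
  }
  NumericVector pk(K1);
  for (int k = 0; k <= K; ++k) {
    double s = 0.0;
    for (int i = 0; i < N; ++i)
      for (int q = 0; q < Q; ++q) s += rprev[id(i, k, q)];
    pk[k] = s;
  }
  // number of time layers the DP buffer holds: the structural memory contract
  int layers = 2;
  return List::create(_["pk"] = pk, _["log_likelihood"] = loglik,
                      _["retained_time_layers"] = layers);
}

// Shared machinery for the two restricted decoders. score_trans(j, i) is the
// log transition term added when moving j -> i (log a_{j,i} for Viterbi,
// 0 / -Inf feasibility mask for posterior-Viterbi); score_emit(t, i) is the
// per-position term (log b + ..., or log gamma).
static List restricted_decode(const NumericMatrix& trans_score,
                              const NumericMatrix& emit_score,
                              const NumericVector& init_score,
                              const IntegerMatrix& delta,
                              const LogicalVector& acc,
                              int l, int u) {
  const int N = trans_score.nrow(), Q = delta.nrow(),
            T = emit_score.nrow(), K1 = u + 1;
  const size_t layer = static_cast<size_t>(N) * K1 * Q;
  std::vector<double> W(layer * T, NEG_INF);
  std::vector<int> BJ(layer * T, -1), BQ(layer * T, -1);
  auto id = [&](int t, int i, int k, int q) {
    return (static_cast<size_t>(t) * N + i) * K1 * Q +
           static_cast<size_t>(k) * Q + q;
  };
  // inverse transitions, sources in ascending order for deterministic ties
  std::vector<std::vector<std::vector<int>>> inv(
      Q, std::vector<std::vector<int>>(N));
  for (int qp = 0; qp < Q; ++qp)
    for (int i = 0; i < N; ++i)
      inv[delta(qp, i) - 1][i].push_back(qp);

  for (int i = 0; i < N; ++i) {
    double v = init_score[i] + emit_score(0, i);
    if (v == NEG_INF || ISNAN(v)) continue;
    int q = delta(0, i) - 1;
    int k = acc[q] ? 1 : 0;
    if (k <= u) W[id(0, i, k, q)] = v;
  }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double em = emit_score(t, i);
      for (int k = 0; k <= u; ++k) {
        for (int q = 0; q < Q; ++q) {
          int kprev = k - (acc[q] ? 1 : 0);
          if (kprev < 0) continue;
          const std::vector<int>& srcs = inv[q][i];
          if (srcs.empty()) continue;
          double best = NEG_INF;
          int bj = -1, bq = -1;
          for (int j = 0; j < N; ++j) {
            double ts = trans_score(j, i);
            if (ts == NEG_INF) continue;
            for (size_t s = 0; s < srcs.size(); ++s) {
              double v = W[id(t - 1, j, kprev, srcs[s])];
              if (v == NEG_INF) continue;
              v += ts;
              if (v > best) { best = v; bj = j; bq = srcs[s]; }
            }
          }
          if (bj >= 0) {
            size_t u_ = id(t, i, k, q);
            W[u_] = best + em;
            BJ[u_] = bj;
            BQ[u_] = bq;
          }
        }
      }
    }
  }
  // per-k feasibility at T (for error reporting) and constrained argmax with
  // tie-break lowest k, then lowest hidden state, then lowest automaton state
  NumericVector feasible(K1, NEG_INF);
  for (int k = 0; k <= u; ++k)
    for (int i = 0; i < N; ++i)
      for (int q = 0; q < Q; ++q) {
        double v = W[id(T - 1, i, k, q)];
        if (v > feasible[k]) feasible[k] = v;
      }
  double best = NEG_INF;
  int bi = -1, bk = -1, bq = -1;
  for (int k = l; k <= u; ++k)
    for (int i = 0; i < N; ++i)
      for (int q = 0; q < Q; ++q) {
        double v = W[id(T - 1, i, k, q)];
        if (v > best) { best = v; bi = i; bk = k; bq = q; }
      }
  if (bi < 0)
    return List::create(_["feasible"] = feasible, _["score"] = NEG_INF);
  IntegerVector path(T);
  int ci = bi, ck = bk, cq = bq;
  path[T - 1] = ci + 1;
  for (int t = T - 1; t >= 1; --t) {
    size_t u_ = id(t, ci, ck, cq);
    int pj = BJ[u_], pq = BQ[u_];
    ck = ck - (acc[cq] ? 1 : 0);
    ci = pj; cq = pq;
    path[t - 1] = ci + 1;
  }
  return List::create(_["path"] = path, _["score"] = best, _["k"] = bk,
                      _["feasible"] = feasible);
}

// Restricted Viterbi: maximises log P(y, x) subject to the occurrence count
// lying in [l, u]. All inputs are log-scaled.
// [[Rcpp::export]]
List rviterbi_cpp(NumericVector logpi, NumericMatrix logA, NumericMatrix logB,
                  IntegerVector yidx, IntegerMatrix delta, LogicalVector acc,
                  int l, int u) {
  const int T = yidx.size(), N = logpi.size();
  NumericMatrix emit(T, N);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) emit(t, i) = logB(i, yidx[t] - 1);
  return restricted_decode(logA, emit, logpi, delta, acc, l, u);
}

// Restricted posterior-Viterbi: maximises sum_t log gamma_t(x_t) over
// syntactically correct paths (mask(j,i) = 0 if a_{j,i} > 0 else -Inf)
// subject to the count constraint. init_mask handles the start state.
// [[Rcpp::export]]
List rpv_cpp(NumericMatrix log_gamma, NumericMatrix mask,
             NumericVector init_mask, IntegerMatrix delta, LogicalVector acc,
             int l, int u) {
  return restricted_decode(mask, log_gamma, init_mask, delta, acc, l, u);
}
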