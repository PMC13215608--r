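#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double phi(double t, int transform) {
  return transform == 1 ? std::sqrt(t) : t;
}

// OMspell edit distance between two canonical spell sequences.
// Operations: insert/delete spell (x,t) at cost indel + e*(phi(t)-phi(1));
// substitute (x,t) <-> (y,u) at cost sub(x,y) + e*|phi(t)-phi(u)|.
static double om_pair(const int* sa, const double* da, int n,
                      const int* sb, const double* db, int m,
                      const NumericMatrix& sub, double indel, double e,
                      int transform) {
  std::vector<double> prev(m + 1), cur(m + 1);
  const double p1 = phi(1.0, transform);
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j)
    prev[j] = prev[j - 1] + indel + e * (phi(db[j - 1], transform) - p1);
  for (int i = 1; i <= n; ++i) {
    const double pa = phi(da[i - 1], transform);
    const double del = indel + e * (pa - p1);
    cur[0] = prev[0] + del;
    for (int j = 1; j <= m; ++j) {
      const double pb = phi(db[j - 1], transform);
      double best = prev[j - 1] + sub(sa[i - 1], sb[j - 1]) + e * std::fabs(pa - pb);
      const double v_del = prev[j] + del;
      if (v_del < best) best = v_del;
      const double v_ins = cur[j - 1] + indel + e * (pb - p1);
      if (v_ins < best) best = v_ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double omspell_pair_cpp(IntegerVector sa, NumericVector da,
                        IntegerVector sb, NumericVector db,
                        NumericMatrix sub, double indel, double e,
                        int transform) {
  return om_pair(INTEGER(sa), REAL(da), sa.size(),
                 INTEGER(sb), REAL(db), sb.size(), sub, indel, e, transform);
}

// Square (cols empty) or rectangular (cols = 1-based indices into the pool)
// OMspell distance matrix. states[i] holds 0-based alphabet indices of the
// i-th pattern's spells, durs[i] the matching durations.
// [[Rcpp::export]]
NumericMatrix omspell_matrix_cpp(List states, List durs, NumericMatrix sub,
                                 double indel, double e, int transform,
                                 IntegerVector cols) {
  const int n = states.size();
  std::vector<IntegerVector> sv(n);
  std::vector<NumericVector> dv(n);
  for (int i = 0; i < n; ++i) {
    sv[i] = states[i];
    dv[i] = durs[i];
  }
  if (cols.size() == 0) {
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d = om_pair(INTEGER(sv[i]), REAL(dv[i]), sv[i].size(),
                           INTEGER(sv[j]), REAL(dv[j]), sv[j].size(),
                           sub, indel, e, transform);
        out(i, j) = d;
        out(j, i) = d;
      }
    }
    return out;
  }
  const int m = cols.size();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const int cj = cols[j] - 1;
    for (int i = 0; i < n; ++i) {
      if (i == cj) { out(i, j) = 0.0; continue; }
      out(i, j) = om_pair(INTEGER(sv[i]), REAL(dv[i]), sv[i].size(),
                          INTEGER(sv[cj]), REAL(dv[cj]), sv[cj].size(),
                          sub, indel, e, transform);
    }
  }
  return out;
}

// Weighted PAM with best-improvement swaps on a precomputed distance matrix.
// med0: 1-based initial medoid indices. Deterministic: candidate swaps are
// scanned in (medoid position, candidate index) order and the largest strict
// decrease wins, first occurrence on ties.
// [[Rcpp::export]]
List pam_cpp(NumericMatrix D, NumericVector w, IntegerVector med0,
             int max_iter) {
  const int n = D.nrow();
  const int k = med0.size();
  std::vector<int> med(k);
  for (int i = 0; i < k; ++i) med[i] = med0[i] - 1;

  std::vector<double> d1(n), d2(n);
  std::vector<int> a1(n);
  auto reassign = [&]() {
    for (int j = 0; j < n; ++j) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int bi = 0;
      for (int c = 0; c < k; ++c) {
        double d = D(j, med[c]);
        if (d < b1) { b2 = b1; b1 = d; bi = c; }
        else if (d < b2) { b2 = d; }
      }
      d1[j] = b1; d2[j] = b2; a1[j] = bi;
    }
  };
  reassign();

  std::vector<bool> is_med(n, false);
  for (int it = 0; it < max_iter; ++it) {
    std::fill(is_med.begin(), is_med.end(), false);
    for (int c = 0; c < k; ++c) is_med[med[c]] = true;
    double best_delta = -1e-12;
    int best_c = -1, best_h = -1;
    for (int c = 0; c < k; ++c) {
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        double delta = 0.0;
        for (int j = 0; j < n; ++j) {
          double base = (a1[j] == c) ? d2[j] : d1[j];
          double dh = D(j, h);
          double nd = dh < base ? dh : base;
          delta += w[j] * (nd - d1[j]);
        }
        if (delta < best_delta) { best_delta = delta; best_c = c; best_h = h; }
      }
    }
    if (best_c < 0) break;
    med[best_c] = best_h;
    reassign();
  }

  double obj = 0.0;
  IntegerVector labels(n);
  IntegerVector medoids(k);
  for (int c = 0; c < k; ++c) medoids[c] = med[c] + 1;
  for (int j = 0; j < n; ++j) {
    labels[j] = a1[j] + 1;
    obj += w[j] * d1[j];
  }
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["objective"] = obj);
}
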