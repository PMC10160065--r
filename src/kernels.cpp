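#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward recursion for the joint pair HMM.  Sequences are 0-based
// integer codes; emit is the flattened |A| x |B| x |H| emission array.
// Rescaling each step keeps the recursion in linear space without underflow
// (the log of the running scale is accumulated), so T in the thousands is safe.
static double forward_joint_core(const int *x, const int *y, int T,
                                 const double *init, const double *trans,
                                 const double *emit, int nH, int nA, int nB) {
  std::vector<double> a(nH), a2(nH);
  double logp = 0.0;
  for (int h = 0; h < nH; ++h)
    a[h] = init[h] * emit[x[0] + nA * (y[0] + (long)nB * h)];
  for (int t = 1; t < T; ++t) {
    double s = 0.0;
    for (int h = 0; h < nH; ++h) s += a[h];
    if (s <= 0.0) return R_NegInf;
    logp += std::log(s);
    for (int h = 0; h < nH; ++h) a[h] /= s;
    for (int h2 = 0; h2 < nH; ++h2) {
      double acc = 0.0;
      for (int h = 0; h < nH; ++h) acc += a[h] * trans[h + nH * h2];
      a2[h2] = acc * emit[x[t] + nA * (y[t] + (long)nB * h2)];
    }
    std::swap(a, a2);
  }
  double s = 0.0;
  for (int h = 0; h < nH; ++h) s += a[h];
  if (s <= 0.0) return R_NegInf;
  return logp + std::log(s);
}

// [[Rcpp::export(name = ".hmm_forward_joint_cpp")]]
double hmm_forward_joint_cpp(IntegerVector x, IntegerVector y,
                             NumericVector init, NumericMatrix trans,
                             NumericVector emit, int nA, int nB) {
  int nH = init.size(), T = x.size();
  return forward_joint_core(INTEGER(x), INTEGER(y), T, REAL(init),
                            REAL(trans), REAL(emit), nH, nA, nB);
}

// Forward recursion for one axis of the model, with the emission table
// marginalised over the other axis (exact-marginal mode).
// emitm is |S| x |H| where S is the axis alphabet.
// [[Rcpp::export(name = ".hmm_forward_marginal_cpp")]]
double hmm_forward_marginal_cpp(IntegerVector s, NumericVector init,
                                NumericMatrix trans, NumericMatrix emitm) {
  int nH = init.size(), T = s.size(), nS = emitm.nrow();
  std::vector<double> a(nH), a2(nH);
  double logp = 0.0;
  for (int h = 0; h < nH; ++h) a[h] = init[h] * emitm[s[0] + nS * h];
  for (int t = 1; t < T; ++t) {
    double sc = 0.0;
    for (int h = 0; h < nH; ++h) sc += a[h];
    if (sc <= 0.0) return R_NegInf;
    logp += std::log(sc);
    for (int h = 0; h < nH; ++h) a[h] /= sc;
    for (int h2 = 0; h2 < nH; ++h2) {
      double acc = 0.0;
      for (int h = 0; h < nH; ++h) acc += a[h] * trans(h, h2);
      a2[h2] = acc * emitm[s[t] + nS * h2];
    }
    std::swap(a, a2);
  }
  double sc = 0.0;
  for (int h = 0; h < nH; ++h) sc += a[h];
  if (sc <= 0.0) return R_NegInf;
  return logp + std::log(sc);
}

// Batched joint forward over candidate pairs.  db / qry are column-major
// T x N integer matrices; pair_i / pair_j are 0-based column indices.
// [[Rcpp::export(name = ".hmm_forward_batch_cpp")]]
NumericVector hmm_forward_batch_cpp(IntegerMatrix db, IntegerMatrix qry,
                                    IntegerVector pair_i, IntegerVector pair_j,
                                    NumericVector init, NumericMatrix trans,
                                    NumericVector emit, int nA, int nB) {
  int T = db.nrow(), nH = init.size(), K = pair_i.size();
  NumericVector out(K);
  const int *dbp = INTEGER(db), *qp = INTEGER(qry);
  for (int k = 0; k < K; ++k) {
    out[k] = forward_joint_core(dbp + (long)T * pair_i[k],
                                qp + (long)T * pair_j[k], T,
                                REAL(init), REAL(trans), REAL(emit),
                                nH, nA, nB);
  }
  return out;
}

// Pair DP for the sequence alignment model, row-rescaled linear space.
// F(i, j) = mf(x_i, y_j) F(i-1, j-1) + df(x_i) F(i-1, j) + if_(y_j) F(i, j-1)
// with F(0, 0) = 1; mf = q_match * P_m, df = q_deletion * P_d,
// if_ = q_insertion * P_i.  Returns log F(n, m).
static double sa_forward_core(const int *x, int n, const int *y, int m,
                              const double *mf, const double *df,
                              const double *iff) {
  std::vector<double> prev(m + 1), cur(m + 1);
  prev[0] = 1.0;
  for (int j = 1; j <= m; ++j) prev[j] = prev[j - 1] * iff[y[j - 1]];
  double logscale = 0.0;
  for (int i = 1; i <= n; ++i) {
    // rescale the previous row by its max to keep values in range
    double mx = 0.0;
    for (int j = 0; j <= m; ++j) if (prev[j] > mx) mx = prev[j];
    if (mx <= 0.0) return R_NegInf;
    for (int j = 0; j <= m; ++j) prev[j] /= mx;
    logscale += std::log(mx);
    const double d = df[x[i - 1]];
    cur[0] = prev[0] * d;
    for (int j = 1; j <= m; ++j) {
      cur[j] = mf[x[i - 1] + 4 * y[j - 1]] * prev[j - 1]
             + d * prev[j]
             + iff[y[j - 1]] * cur[j - 1];
    }
    std::swap(prev, cur);
  }
  if (prev[m] <= 0.0) return R_NegInf;
  return logscale + std::log(prev[m]);
}

// [[Rcpp::export(name = ".sa_forward_cpp")]]
double sa_forward_cpp(IntegerVector x, IntegerVector y, NumericMatrix mf,
                      NumericVector df, NumericVector iff) {
  return sa_forward_core(INTEGER(x), x.size(), INTEGER(y), y.size(),
                         REAL(mf), REAL(df), REAL(iff));
}

// Windowed (glocal) likelihood-ratio DP: the read y must be consumed in
// full, while any prefix/suffix of the window x is left to the background
// model for free.  Factors arrive already divided by the background
// (mfn = q_m P_m / (bx by), dfn = q_d P_d / bx, ifn = q_i P_i / by), so the
// DP accumulates likelihood *ratios* and sums them over every alignment of y
// to every substring of x.  R(i, 0) = 1 restarts an alignment at window
// offset i; the result is log sum_i R(i, m).  Rows are rescaled downward
// only, so restarts stay representable until real signal mass dominates.
static double sa_window_core(const int *x, int n, const int *y, int m,
                             const double *mfn, const double *dfn,
                             const double *ifn) {
  const double BIG = 1e100;
  std::vector<double> prev(m + 1), cur(m + 1);
  double logscale = 0.0, acc = R_NegInf;
  prev[0] = 1.0;
  for (int j = 1; j <= m; ++j) prev[j] = prev[j - 1] * ifn[y[j - 1]];
  if (prev[m] > 0) acc = std::log(prev[m]);
  for (int i = 1; i <= n; ++i) {
    double mx = 0.0;
    for (int j = 0; j <= m; ++j) if (prev[j] > mx) mx = prev[j];
    if (mx > BIG) {
      for (int j = 0; j <= m; ++j) prev[j] /= mx;
      logscale += std::log(mx);
    }
    const double d = dfn[x[i - 1]];
    double restart = (logscale < 700.0) ? std::exp(-logscale) : 0.0;
    cur[0] = prev[0] * d + restart;
    for (int j = 1; j <= m; ++j) {
      cur[j] = mfn[x[i - 1] + 4 * y[j - 1]] * prev[j - 1]
             + d * prev[j]
             + ifn[y[j - 1]] * cur[j - 1];
    }
    std::swap(prev, cur);
    if (prev[m] > 0) {
      double v = logscale + std::log(prev[m]);
      if (acc == R_NegInf) acc = v;
      else {
        double hi = std::max(acc, v), lo = std::min(acc, v);
        acc = hi + std::log1p(std::exp(lo - hi));
      }
    }
  }
  return acc;
}

// [[Rcpp::export(name = ".sa_window_llr_cpp")]]
double sa_window_llr_cpp(IntegerVector x, IntegerVector y, NumericMatrix mfn,
                         NumericVector dfn, NumericVector ifn) {
  return sa_window_core(INTEGER(x), x.size(), INTEGER(y), y.size(),
                        REAL(mfn), REAL(dfn), REAL(ifn));
}

// [[Rcpp::export(name = ".sa_window_llr_batch_cpp")]]
NumericVector sa_window_llr_batch_cpp(List xs, List ys, NumericMatrix mfn,
                                      NumericVector dfn, NumericVector ifn) {
  int K = xs.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector x = xs[k], y = ys[k];
    out[k] = sa_window_core(INTEGER(x), x.size(), INTEGER(y), y.size(),
                            REAL(mfn), REAL(dfn), REAL(ifn));
  }
  return out;
}

// [[Rcpp::export(name = ".sa_forward_batch_cpp")]]
NumericVector sa_forward_batch_cpp(List xs, List ys, NumericMatrix mf,
                                   NumericVector df, NumericVector iff) {
  int K = xs.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector x = xs[k], y = ys[k];
    out[k] = sa_forward_core(INTEGER(x), x.size(), INTEGER(y), y.size(),
                             REAL(mf), REAL(df), REAL(iff));
  }
  return out;
}
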