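#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Pointwise cost: absolute difference (Euclidean distance for scalars).
static inline double pcost(double a, double b) { return std::fabs(a - b); }

static const double INF = std::numeric_limits<double>::infinity();

// Full DTW between two series with backtracking.
// Recurrence: D(i,j) = |x_i - y_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1)),
// first row/column cumulative. Backtracking prefers the diagonal step on
// ties, then the vertical (stream) step. Path indices returned 1-based.
// [[Rcpp::export]]
List cpp_dtw_full(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input series");
  NumericMatrix D(n, m);
  D(0, 0) = pcost(x[0], y[0]);
  for (int i = 1; i < n; ++i) D(i, 0) = D(i - 1, 0) + pcost(x[i], y[0]);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + pcost(x[0], y[j]);
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = pcost(x[i], y[j]) + best;
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      const double d = D(i - 1, j - 1), v = D(i - 1, j), h = D(i, j - 1);
      if (d <= v && d <= h) { --i; --j; }
      else if (v <= h)      { --i; }
      else                  { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  NumericVector costs(L);
  for (int k = 0; k < L; ++k) {
    const int ii = pi[L - 1 - k], jj = pj[L - 1 - k];
    path(k, 0) = ii + 1;
    path(k, 1) = jj + 1;
    costs[k] = pcost(x[ii], y[jj]);
  }
  return List::create(_["distance"] = D(n - 1, m - 1),
                      _["path"] = path,
                      _["costs"] = costs,
                      _["mean_cost"] = D(n - 1, m - 1) / (double)L);
}

// d_t series: for each stream prefix x[0..t], the accumulated DTW distance
// against the FULL template y, i.e. the last row of the full DP table.
// [[Rcpp::export]]
NumericVector cpp_dtw_lastrow(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input series");
  std::vector<double> prev(m), cur(m);
  NumericVector out(n);
  prev[0] = pcost(x[0], y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + pcost(x[0], y[j]);
  out[0] = prev[m - 1];
  for (int t = 1; t < n; ++t) {
    cur[0] = prev[0] + pcost(x[t], y[0]);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = pcost(x[t], y[j]) + best;
    }
    out[t] = cur[m - 1];
    std::swap(prev, cur);
  }
  return out;
}

// Advance one streaming DP column. `col` is the accumulated-distance column
// for the previous stream sample (empty on initialisation).
// [[Rcpp::export]]
NumericVector cpp_dtw_advance(NumericVector col, double xt, NumericVector y) {
  const int m = y.size();
  if (m == 0) stop("dtw: empty template");
  NumericVector out(m);
  if (col.size() == 0) {
    out[0] = pcost(xt, y[0]);
    for (int j = 1; j < m; ++j) out[j] = out[j - 1] + pcost(xt, y[j]);
    return out;
  }
  if (col.size() != m) stop("dtw: state/template length mismatch");
  out[0] = col[0] + pcost(xt, y[0]);
  for (int j = 1; j < m; ++j) {
    double best = col[j - 1];
    if (col[j] < best) best = col[j];
    if (out[j - 1] < best) best = out[j - 1];
    out[j] = pcost(xt, y[j]) + best;
  }
  return out;
}

// SPRING subsequence matching (Sakurai et al. style): subsequences of x may
// start at any sample (d(t,0) = cost), start pointers are propagated with the
// minimising predecessor, and a match (ts, te, dmin) is reported once the
// running template-end distance dmin <= tau cannot be improved by any pending
// warping path that overlaps it. Indices in the returned matrix are 1-based.
// [[Rcpp::export]]
List cpp_spring(NumericVector x, NumericVector y, double tau) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("spring: empty input series");
  std::vector<double> d(m, INF), dn(m);
  std::vector<int> s(m, 0), sn(m);
  NumericVector dm(n);
  std::vector<double> ms, me, md;
  double dmin = INF;
  int ts = -1, te = -1;
  for (int t = 0; t < n; ++t) {
    dn[0] = pcost(x[t], y[0]);
    sn[0] = t;
    for (int j = 1; j < m; ++j) {
      double best = d[j - 1]; int bs = s[j - 1];          // diagonal
      if (d[j] < best) { best = d[j]; bs = s[j]; }        // vertical (stream)
      if (dn[j - 1] < best) { best = dn[j - 1]; bs = sn[j - 1]; } // horizontal
      dn[j] = pcost(x[t], y[j]) + best;
      sn[j] = bs;
    }
    if (dmin <= tau) {
      bool confirmed = true;
      for (int j = 0; j < m; ++j) {
        if (dn[j] < dmin && sn[j] <= te) { confirmed = false; break; }
      }
      if (confirmed) {
        ms.push_back(ts + 1); me.push_back(te + 1); md.push_back(dmin);
        dmin = INF;
        for (int j = 0; j < m; ++j) if (sn[j] <= te) dn[j] = INF;
      }
    }
    if (dn[m - 1] <= tau && dn[m - 1] < dmin) {
      dmin = dn[m - 1]; ts = sn[m - 1]; te = t;
    }
    dm[t] = dn[m - 1];
    std::swap(d, dn);
    std::swap(s, sn);
  }
  if (dmin <= tau) {  // flush pending match at stream end
    ms.push_back(ts + 1); me.push_back(te + 1); md.push_back(dmin);
  }
  const int K = (int)ms.size();
  NumericMatrix matches(K, 3);
  for (int k = 0; k < K; ++k) {
    matches(k, 0) = ms[k]; matches(k, 1) = me[k]; matches(k, 2) = md[k];
  }
  return List::create(_["matches"] = matches, _["dm"] = dm);
}
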