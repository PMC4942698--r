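// Inner kernels for the lagged sequenceness statistic.
//
// The statistic itself is defined (and independently verified) in R; these
// routines only restate it in terms of per-lag segment moments so that
// permutation nulls over many shuffles x trials stay fast. For a lag d and
// trial matrix X (n x K), with A = X[0..n-d-1, ] and B = X[d..n-1, ]
// (centered within segment), all per-state correlations against any
// transition matrix M derive from C = A'B, S = A'A and v2 = colSums(B^2):
//   cov_j  = sum_i M(i,j) C(i,j)
//   var1_j = sum_{i,k} M(i,j) M(k,j) S(i,k),
// and forward_j = cov_j / sqrt(var1_j * v2_j) (0 if degenerate).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Segment moments for one lag. C, S are K x K buffers, v2 length K.
void lag_moments(const NumericMatrix& X, int d,
                 std::vector<double>& C, std::vector<double>& S,
                 std::vector<double>& v2) {
  const int n = X.nrow(), K = X.ncol(), m = n - d;
  std::vector<double> ma(K, 0.0), mb(K, 0.0);
  for (int j = 0; j < K; ++j) {
    double sa = 0.0, sb = 0.0;
    for (int t = 0; t < m; ++t) {
      sa += X(t, j);
      sb += X(t + d, j);
    }
    ma[j] = sa / m;
    mb[j] = sb / m;
  }
  std::fill(C.begin(), C.end(), 0.0);
  std::fill(S.begin(), S.end(), 0.0);
  std::fill(v2.begin(), v2.end(), 0.0);
  for (int t = 0; t < m; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = X(t, i) - ma[i];
      for (int j = 0; j < K; ++j) {
        C[i + K * j] += ai * (X(t + d, j) - mb[j]);
        S[i + K * j] += ai * (X(t, j) - ma[j]);
      }
    }
    for (int j = 0; j < K; ++j) {
      const double bj = X(t + d, j) - mb[j];
      v2[j] += bj * bj;
    }
  }
}

// mean over states of per-state correlation for transition matrix M
// (column-major K x K), given segment moments.
double mean_corr(const std::vector<double>& M, const std::vector<double>& C,
                 const std::vector<double>& S, const std::vector<double>& v2,
                 int K, bool transpose) {
  const double eps = 1e-12;
  double acc = 0.0;
  for (int j = 0; j < K; ++j) {
    double cov = 0.0, var1 = 0.0;
    for (int i = 0; i < K; ++i) {
      const double mij = transpose ? M[j + K * i] : M[i + K * j];
      cov += mij * C[i + K * j];
      for (int k = 0; k < K; ++k) {
        const double mkj = transpose ? M[j + K * k] : M[k + K * j];
        var1 += mij * mkj * S[i + K * k];
      }
    }
    const double den2 = var1 * v2[j];
    if (den2 > eps * eps) acc += cov / std::sqrt(den2);
  }
  return acc / K;
}

} // namespace

// [[Rcpp::export(name = ".cpp_diff_curve")]]
NumericVector cpp_diff_curve(const NumericMatrix& X, const NumericMatrix& Tm,
                             const IntegerVector& lag_bins) {
  const int K = X.ncol();
  std::vector<double> M(Tm.begin(), Tm.end());
  std::vector<double> C(K * K), S(K * K), v2(K);
  NumericVector out(lag_bins.size());
  for (int li = 0; li < lag_bins.size(); ++li) {
    lag_moments(X, lag_bins[li], C, S, v2);
    out[li] = mean_corr(M, C, S, v2, K, false) -
              mean_corr(M, C, S, v2, K, true);
  }
  return out;
}

// forward and reverse curves (rows 1 and 2) for a single transition matrix.
// [[Rcpp::export(name = ".cpp_fr_curve")]]
NumericMatrix cpp_fr_curve(const NumericMatrix& X, const NumericMatrix& Tm,
                           const IntegerVector& lag_bins) {
  const int K = X.ncol();
  std::vector<double> M(Tm.begin(), Tm.end());
  std::vector<double> C(K * K), S(K * K), v2(K);
  NumericMatrix out(2, lag_bins.size());
  for (int li = 0; li < lag_bins.size(); ++li) {
    lag_moments(X, lag_bins[li], C, S, v2);
    out(0, li) = mean_corr(M, C, S, v2, K, false);
    out(1, li) = mean_corr(M, C, S, v2, K, true);
  }
  return out;
}

// Sample-order null for one trial: rows of X are re-ordered by each column
// of `order` (1-based sample permutations) and the forward-minus-reverse
// curve is recomputed. Prefix sums give segment means/variances in O(1) per
// lag; only the lagged cross terms are O(n). Returns shuffles x lags.
// [[Rcpp::export(name = ".cpp_sample_null")]]
NumericMatrix cpp_sample_null(const NumericMatrix& X, const NumericMatrix& Tm,
                              const IntegerVector& lag_bins,
                              const IntegerMatrix& order) {
  const int n = X.nrow(), K = X.ncol();
  const int nS = order.ncol(), nL = lag_bins.size();
  const double eps = 1e-12;
  // project through the transitions once; row shuffles commute with this
  NumericMatrix XF(n, K), XR(n, K);
  for (int j = 0; j < K; ++j) {
    for (int t = 0; t < n; ++t) {
      double f = 0.0, r = 0.0;
      for (int i = 0; i < K; ++i) {
        f += X(t, i) * Tm(i, j);
        r += X(t, i) * Tm(j, i);
      }
      XF(t, j) = f;
      XR(t, j) = r;
    }
  }
  NumericMatrix out(nS, nL);
  std::vector<double> a(n), b(n), c(n);
  std::vector<double> pa(n + 1), pa2(n + 1), pb(n + 1), pb2(n + 1),
      pc(n + 1), pc2(n + 1);
  for (int s = 0; s < nS; ++s) {
    for (int j = 0; j < K; ++j) {
      for (int t = 0; t < n; ++t) {
        const int u = order(t, s) - 1;
        a[t] = XF(u, j);
        b[t] = X(u, j);
        c[t] = XR(u, j);
      }
      pa[0] = pa2[0] = pb[0] = pb2[0] = pc[0] = pc2[0] = 0.0;
      for (int t = 0; t < n; ++t) {
        pa[t + 1] = pa[t] + a[t];
        pa2[t + 1] = pa2[t] + a[t] * a[t];
        pb[t + 1] = pb[t] + b[t];
        pb2[t + 1] = pb2[t] + b[t] * b[t];
        pc[t + 1] = pc[t] + c[t];
        pc2[t + 1] = pc2[t] + c[t] * c[t];
      }
      for (int li = 0; li < nL; ++li) {
        const int d = lag_bins[li], m = n - d;
        double xf = 0.0, xr = 0.0;
        for (int t = 0; t < m; ++t) {
          xf += a[t] * b[t + d];
          xr += c[t] * b[t + d];
        }
        const double sa = pa[m], sb = pb[n] - pb[d], sc = pc[m];
        const double va = pa2[m] - sa * sa / m;
        const double vb = (pb2[n] - pb2[d]) - sb * sb / m;
        const double vc = pc2[m] - sc * sc / m;
        const double covf = xf - sa * sb / m;
        const double covr = xr - sc * sb / m;
        double rf = 0.0, rr = 0.0;
        if (va * vb > eps * eps) rf = covf / std::sqrt(va * vb);
        if (vc * vb > eps * eps) rr = covr / std::sqrt(vc * vb);
        out(s, li) += (rf - rr) / K;
      }
    }
  }
  return out;
}

// perms: list of 1-based permutation vectors sigma; the permuted matrix is
// M[a,b] = Tm[sigma[a], sigma[b]]. Returns perms x lags matrix of diff
// values for a single trial.
// [[Rcpp::export(name = ".cpp_diff_perms")]]
NumericMatrix cpp_diff_perms(const NumericMatrix& X, const NumericMatrix& Tm,
                             const List& perms,
                             const IntegerVector& lag_bins) {
  const int K = X.ncol();
  const int nP = perms.size(), nL = lag_bins.size();
  std::vector<std::vector<double> > Ms(nP, std::vector<double>(K * K));
  for (int p = 0; p < nP; ++p) {
    IntegerVector sig = perms[p];
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b)
        Ms[p][a + K * b] = Tm(sig[a] - 1, sig[b] - 1);
  }
  std::vector<double> C(K * K), S(K * K), v2(K);
  NumericMatrix out(nP, nL);
  for (int li = 0; li < nL; ++li) {
    lag_moments(X, lag_bins[li], C, S, v2);
    for (int p = 0; p < nP; ++p) {
      out(p, li) = mean_corr(Ms[p], C, S, v2, K, false) -
                   mean_corr(Ms[p], C, S, v2, K, true);
    }
  }
  return out;
}
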