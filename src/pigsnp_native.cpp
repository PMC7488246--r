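#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline double soft_threshold(double z, double a) {
  if (z > a) return z - a;
  if (z < -a) return z + a;
  return 0.0;
}

// Cyclic coordinate descent for
//   (1 / (2 n)) * ||X w - y||_2^2 + alpha * ||w||_1
// X and y are expected already centred (intercept handled by the caller).
// Alternates sweeps over the active set with full sweeps; converged when the
// largest coefficient update in a full sweep is below tol.
// [[Rcpp::export]]
List lasso_cd_cpp(NumericMatrix X, NumericVector y, double alpha,
                  NumericVector w0, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> r(n);     // residual y - X w
  std::vector<double> s(p);     // (x_j . x_j) / n

  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += xj[i] * xj[i];
    s[j] = ss / n;
    if (w[j] != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * w[j];
    }
  }

  auto sweep = [&](const std::vector<int>& idx) -> double {
    double max_delta = 0.0;
    for (int j : idx) {
      if (s[j] <= 0.0) { w[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
      double z = dot / n + w[j] * s[j];
      double wj_new = soft_threshold(z, alpha) / s[j];
      double d = wj_new - w[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
        w[j] = wj_new;
      }
      double ad = std::abs(d);
      if (ad > max_delta) max_delta = ad;
    }
    return max_delta;
  };

  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;

  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    double md = sweep(all);
    ++iter;
    if (md < tol) { converged = true; break; }
    // iterate on the active set until it stabilises, then re-check all
    std::vector<int> active;
    active.reserve(p);
    for (int j = 0; j < p; ++j) if (w[j] != 0.0) active.push_back(j);
    while (iter < max_iter && !active.empty()) {
      double mda = sweep(active);
      ++iter;
      if (mda < tol) break;
    }
  }

  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += r[i] * r[i];
  obj /= (2.0 * n);
  for (int j = 0; j < p; ++j) obj += alpha * std::abs(w[j]);

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["objective"] = obj);
}

// Kraskov-Stoegbauer-Grassberger (variant 1) mutual information estimate for a
// continuous pair, Chebyshev (max) norm:
//   MI = psi(k) + psi(N) - < psi(nx_i + 1) + psi(ny_i + 1) >
// where nx_i counts points with |x_j - x_i| strictly less than the distance to
// the k-th joint-space neighbour. Caller breaks ties with jitter.
// [[Rcpp::export]]
double mi_knn_cc_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k >= n) stop("k must be smaller than the number of samples");
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = std::abs(x[j] - x[i]);
      double dy = std::abs(y[j] - y[i]);
      d[j] = dx > dy ? dx : dy;
    }
    d[i] = R_PosInf;  // exclude self
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::abs(x[j] - x[i]) < eps) ++nx;
      if (std::abs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Mixed discrete/continuous mutual information (Ross 2014): x holds group ids
// (1-based), y is continuous. Singleton groups carry no within-class
// neighbourhood and are dropped, mirroring the standard implementation.
//   MI = psi(N) - < psi(n_class_i) > + < psi(k_i) > - < psi(m_i) >
// with k_i = min(k, n_class_i - 1), d_i the k_i-th within-class distance in y,
// m_i the number of other retained points with |y_j - y_i| <= d_i.
// psi_tab[t] = digamma(t) precomputed for t = 1..n (all arguments are integer).
static double mi_dc_impl(const int* x, const double* y, int n, int k,
                         const std::vector<double>& psi_tab) {
  int g = 0;
  for (int i = 0; i < n; ++i) if (x[i] > g) g = x[i];
  std::vector<int> count(g + 1, 0);
  for (int i = 0; i < n; ++i) count[x[i]]++;

  // bucket retained indices by class; sorted y over the retained set for the
  // radius counts
  std::vector<std::vector<int> > members(g + 1);
  std::vector<double> ykeep;
  ykeep.reserve(n);
  int m = 0;
  for (int i = 0; i < n; ++i) {
    if (count[x[i]] > 1) {
      members[x[i]].push_back(i);
      ykeep.push_back(y[i]);
      ++m;
    }
  }
  if (m < 2) return 0.0;
  std::sort(ykeep.begin(), ykeep.end());

  double acc = 0.0;
  std::vector<double> din;
  din.reserve(m);
  for (int c = 1; c <= g; ++c) {
    const std::vector<int>& mem = members[c];
    const int nc = (int)mem.size();
    if (nc < 2) continue;
    const int ki = std::min(k, nc - 1);
    for (int a = 0; a < nc; ++a) {
      const int i = mem[a];
      din.clear();
      for (int b = 0; b < nc; ++b) {
        if (b != a) din.push_back(std::abs(y[mem[b]] - y[i]));
      }
      std::nth_element(din.begin(), din.begin() + (ki - 1), din.end());
      const double eps = din[ki - 1];
      // retained points with |y_j - y_i| <= eps, excluding self; widen the
      // interval by one ulp so the k-th neighbour itself is never lost to
      // rounding of y[i] +/- eps
      const double hi = std::nextafter(y[i] + eps, R_PosInf);
      const double lo = std::nextafter(y[i] - eps, R_NegInf);
      int cnt = (int)(std::upper_bound(ykeep.begin(), ykeep.end(), hi) -
                      std::lower_bound(ykeep.begin(), ykeep.end(), lo)) - 1;
      if (cnt < 1) cnt = 1;
      acc += psi_tab[ki] - psi_tab[nc] - psi_tab[cnt];
    }
  }
  return psi_tab[m] + acc / m;
}

static std::vector<double> make_psi_tab(int n) {
  std::vector<double> tab(n + 1, 0.0);
  for (int t = 1; t <= n; ++t) tab[t] = R::digamma((double)t);
  return tab;
}

// [[Rcpp::export]]
double mi_knn_dc_cpp(IntegerVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k >= n) stop("k must be smaller than the number of samples");
  std::vector<double> psi_tab = make_psi_tab(n);
  return mi_dc_impl(&x[0], &y[0], n, k, psi_tab);
}

// Column-wise mixed-estimator MI for a genotype matrix: Xg holds per-column
// group ids (1-based), y continuous (jittered).
// [[Rcpp::export]]
NumericVector mi_knn_dc_matrix_cpp(IntegerMatrix Xg, NumericVector y, int k) {
  const int n = Xg.nrow(), p = Xg.ncol();
  if (k >= n) stop("k must be smaller than the number of samples");
  std::vector<double> psi_tab = make_psi_tab(n);
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    double v = mi_dc_impl(&Xg(0, j), &y[0], n, k, psi_tab);
    out[j] = v > 0.0 ? v : 0.0;
  }
  return out;
}
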