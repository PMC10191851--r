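#include <Rcpp.h>
#include <cmath>
#include <vector>

// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// eigenproblem (Slepian 1978): the DPSS are eigenvectors of the matrix with
//   diag(t)    = ((N-1-2t)/2)^2 * cos(2*pi*W),  t = 0..N-1
//   offdiag(t) = t*(N-t)/2,                     t = 1..N-1
// ordered by eigenvalue. The top K eigenvalues are isolated by Sturm-count
// bisection and the eigenvectors recovered by inverse iteration with a
// partially pivoted tridiagonal solve, which is O(N) per taper and so
// remains practical for minute-long recordings.

namespace {

// number of eigenvalues of the tridiagonal (d, e) strictly below x
int sturm_count(const std::vector<double>& d, const std::vector<double>& e,
                double x) {
  const int n = (int)d.size();
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    double denom = (q == 0.0) ? 1e-300 : q;
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// solve (T - shift I) x = b, T tridiagonal, Gaussian elimination with
// partial pivoting (fill-in limited to a second superdiagonal)
void solve_shifted(const std::vector<double>& d, const std::vector<double>& e,
                   double shift, std::vector<double>& b) {
  const int n = (int)d.size();
  std::vector<double> low(n, 0.0), dia(n), up1(n, 0.0), up2(n, 0.0);
  for (int i = 0; i < n; ++i) dia[i] = d[i] - shift;
  for (int i = 0; i + 1 < n; ++i) { low[i] = e[i]; up1[i] = e[i]; }
  // forward elimination
  for (int i = 0; i + 1 < n; ++i) {
    if (std::fabs(low[i]) > std::fabs(dia[i])) {
      std::swap(dia[i], low[i]);
      std::swap(up1[i], dia[i + 1]);
      std::swap(up2[i], up1[i + 1]);
      std::swap(b[i], b[i + 1]);
    }
    double piv = (dia[i] == 0.0) ? 1e-300 : dia[i];
    double m = low[i] / piv;
    dia[i + 1] -= m * up1[i];
    up1[i + 1] -= m * up2[i];
    b[i + 1] -= m * b[i];
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= up1[i] * b[i + 1];
    if (i + 2 < n) s -= up2[i] * b[i + 2];
    double piv = (dia[i] == 0.0) ? 1e-300 : dia[i];
    b[i] = s / piv;
  }
}

}  // namespace

// [[Rcpp::export(name = ".dpss_tapers")]]
Rcpp::NumericMatrix dpss_tapers(int n, double nw, int k) {
  if (n < 2) Rcpp::stop("taper length must be at least 2");
  if (k < 1 || k > n) Rcpp::stop("invalid number of tapers");
  const double W = nw / n;
  const double c = std::cos(2.0 * M_PI * W);
  std::vector<double> d(n), e(n - 1);
  for (int t = 0; t < n; ++t) {
    double h = (n - 1.0 - 2.0 * t) / 2.0;
    d[t] = h * h * c;
  }
  for (int t = 1; t < n; ++t) e[t - 1] = t * (n - t) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < n - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  const double scale = std::max(std::fabs(lo), std::fabs(hi));
  const double tol = 1e-13 * scale;

  Rcpp::NumericMatrix tapers(n, k);
  for (int j = 0; j < k; ++j) {
    // j-th largest eigenvalue = eigenvalue with index n-1-j (ascending);
    // bisect for x with sturm_count(x) == n-1-j from above
    int target = n - 1 - j;  // want count(lambda-) == target
    double a = lo, b = hi;
    while (b - a > tol) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) > target) b = mid; else a = mid;
    }
    double lambda = 0.5 * (a + b);

    // inverse iteration from a fixed deterministic start
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = 1.0 + 0.5 * std::sin(1.0 + i);
    for (int it = 0; it < 4; ++it) {
      solve_shifted(d, e, lambda, v);
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // re-orthogonalise against previous tapers (guards clustered eigenvalues)
    for (int p = 0; p < j; ++p) {
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += v[i] * tapers(i, p);
      if (std::fabs(dot) > 1e-8) {
        for (int i = 0; i < n; ++i) v[i] -= dot * tapers(i, p);
        double nrm = 0.0;
        for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
        nrm = std::sqrt(nrm);
        for (int i = 0; i < n; ++i) v[i] /= nrm;
      }
    }
    // Slepian polarity convention: symmetric tapers have positive mean,
    // antisymmetric tapers start with a positive lobe
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += v[i];
    bool flip;
    if (j % 2 == 0) {
      flip = mean < 0;
    } else {
      double s = 0.0;
      for (int i = 0; i < n / 2; ++i) s += v[i];
      flip = s < 0;
    }
    for (int i = 0; i < n; ++i) tapers(i, j) = flip ? -v[i] : v[i];
  }
  return tapers;
}
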