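#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RBF kernel matrix K[i, j] = exp(-gamma * ||X_i - Y_j||^2) between row sets.
// ---------------------------------------------------------------------------
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_rbf_kernel(NumericMatrix X, NumericMatrix Y, double gamma) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("dimension mismatch between X and Y");
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}

// ---------------------------------------------------------------------------
// SMO solver for the binary C-SVC dual with a precomputed kernel matrix.
//
// Minimise 1/2 a'Qa - e'a  with  Q_ij = y_i y_j K_ij,  0 <= a_i <= C,
// y'a = 0.  Working-set selection is the classical maximal violating pair;
// the decision function is f(x) = sum_i a_i y_i K(x_i, x) - rho.
// ---------------------------------------------------------------------------
// [[Rcpp::export(rng = false)]]
List cpp_smo(NumericMatrix K, NumericVector y, double C,
             double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double *Kp = K.begin();       // symmetric: row i == column i
  const double *yp = y.begin();

  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    m_up = -HUGE_VAL;
    m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -yp[t] * G[t];
      const bool in_up = (yp[t] > 0 && alpha[t] < C) || (yp[t] < 0 && alpha[t] > 0);
      const bool in_low = (yp[t] > 0 && alpha[t] > 0) || (yp[t] < 0 && alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    const double ci = yp[i] * dai, cj = yp[j] * daj;
    const double *Ki = Kp + (size_t)i * n, *Kj = Kp + (size_t)j * n;
    for (int t = 0; t < n; ++t)
      G[t] += yp[t] * (ci * Ki[t] + cj * Kj[t]);
  }

  // rho from free support vectors, else midpoint of the violating bounds
  double rho;
  int n_free = 0;
  double sum_free = 0.0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      sum_free += y[t] * G[t];
      ++n_free;
    }
  }
  if (n_free > 0) rho = sum_free / n_free;
  else rho = -(m_up + m_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter,
                      _["converged"] = iter < max_iter);
}

// ---------------------------------------------------------------------------
// 4th-order gammatone filterbank: per-filter RMS of one analysis frame.
//
// Each filter is a cascade of four identical complex one-pole sections with
// pole r * exp(i * 2*pi*fc/fs), r = exp(-2*pi*b/fs), b = 1.019 * ERB(fc).
// The cascade is peak-normalised (gain 1 at fc; factor 2 recovers the real
// envelope from the analytic response).
// ---------------------------------------------------------------------------
// [[Rcpp::export(rng = false)]]
NumericVector cpp_gammatone_rms(NumericVector frame, NumericVector fc, double fs) {
  const int n = frame.size(), nf = fc.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    const double erb = 24.7 * (4.37 * fc[f] / 1000.0 + 1.0);
    const double b = 1.019 * erb;
    const double r = std::exp(-2.0 * M_PI * b / fs);
    const double phi = 2.0 * M_PI * fc[f] / fs;
    const std::complex<double> p = std::polar(r, phi);
    const double norm = 2.0 * std::pow(1.0 - r, 4.0);
    std::complex<double> s1(0, 0), s2(0, 0), s3(0, 0), s4(0, 0);
    double acc = 0.0;
    for (int t = 0; t < n; ++t) {
      s1 = frame[t] + p * s1;
      s2 = s1 + p * s2;
      s3 = s2 + p * s3;
      s4 = s3 + p * s4;
      const double yt = norm * s4.real();
      acc += yt * yt;
    }
    out[f] = std::sqrt(acc / n);
  }
  return out;
}
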