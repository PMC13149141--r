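#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (xs, ys), evaluated at integer grid 0..n-1.
// xs strictly increasing; eval points outside [xs.front, xs.back] use the
// terminal cubic pieces (extrapolation only occurs within mirrored padding).
static void spline_eval(const std::vector<double> &xs,
                        const std::vector<double> &ys,
                        int n, std::vector<double> &out) {
  const int k = (int)xs.size();
  if (k == 2) { // straight line
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int i = 0; i < n; ++i) out[i] = ys[0] + slope * (i - xs[0]);
    return;
  }
  // second derivatives via tridiagonal solve (natural BCs)
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), m2(k);
  for (int i = 0; i < k - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[k - 1] = 1.0; z[k - 1] = 0.0; m2[k - 1] = 0.0;
  for (int j = k - 2; j >= 0; --j) m2[j] = z[j] - mu[j] * m2[j + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < k - 2 && x > xs[seg + 1]) ++seg;
    double dx = xs[seg + 1] - xs[seg];
    double a = (xs[seg + 1] - x) / dx, b = (x - xs[seg]) / dx;
    out[i] = a * ys[seg] + b * ys[seg + 1] +
      ((a * a * a - a) * m2[seg] + (b * b * b - b) * m2[seg + 1]) * dx * dx / 6.0;
  }
}

// Local extrema of h; plateaus take the first sample of the plateau.
static void find_extrema(const std::vector<double> &h,
                         std::vector<int> &imax, std::vector<int> &imin) {
  imax.clear(); imin.clear();
  const int n = (int)h.size();
  for (int i = 1; i < n - 1; ++i) {
    if (h[i] > h[i - 1] && h[i] >= h[i + 1]) imax.push_back(i);
    else if (h[i] < h[i - 1] && h[i] <= h[i + 1]) imin.push_back(i);
  }
}

// Mirror up to two boundary extrema across each end so the envelope spline
// has support over the full record.
static void pad_extrema(const std::vector<int> &idx,
                        const std::vector<double> &h, int n,
                        std::vector<double> &xs, std::vector<double> &ys) {
  xs.clear(); ys.clear();
  const int k = (int)idx.size();
  int npadl = std::min(2, k), npadr = std::min(2, k);
  for (int j = npadl - 1; j >= 0; --j) {
    double x = -(double)idx[j];
    if (x < -(double)(n)) continue;
    xs.push_back(x); ys.push_back(h[idx[j]]);
  }
  for (int j = 0; j < k; ++j) { xs.push_back((double)idx[j]); ys.push_back(h[idx[j]]); }
  for (int j = 0; j < npadr; ++j) {
    double x = 2.0 * (n - 1) - (double)idx[k - 1 - j];
    xs.push_back(x); ys.push_back(h[idx[k - 1 - j]]);
  }
  // enforce strict increase (mirroring of an extremum at the end sample)
  for (size_t j = 1; j < xs.size();) {
    if (xs[j] <= xs[j - 1]) { xs.erase(xs.begin() + j); ys.erase(ys.begin() + j); }
    else ++j;
  }
}

// One EMD of x: fixed number of sifting iterations per mode.
// Returns modes by column; res receives the residual.
static int emd_one(std::vector<double> x, int nsift, int max_imf,
                   std::vector<std::vector<double> > &modes,
                   std::vector<double> &res) {
  const int n = (int)x.size();
  std::vector<int> imax, imin;
  std::vector<double> xs, ys, up(n), lo(n), h(n);
  int nmodes = 0;
  for (int m = 0; m < max_imf; ++m) {
    find_extrema(x, imax, imin);
    if ((int)imax.size() + (int)imin.size() < 4) break;
    h = x;
    for (int s = 0; s < nsift; ++s) {
      find_extrema(h, imax, imin);
      if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
      pad_extrema(imax, h, n, xs, ys);
      spline_eval(xs, ys, n, up);
      pad_extrema(imin, h, n, xs, ys);
      spline_eval(xs, ys, n, lo);
      for (int i = 0; i < n; ++i) h[i] -= 0.5 * (up[i] + lo[i]);
    }
    modes[nmodes] = h;
    for (int i = 0; i < n; ++i) x[i] -= h[i];
    ++nmodes;
  }
  res = x;
  return nmodes;
}

// [[Rcpp::export(name = ".emd_cpp")]]
NumericMatrix emd_cpp(NumericVector x, int nsift, int max_imf) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), res;
  std::vector<std::vector<double> > modes(max_imf);
  int nm = emd_one(xv, nsift, max_imf, modes, res);
  NumericMatrix out(n, nm + 1);
  for (int m = 0; m < nm; ++m)
    for (int i = 0; i < n; ++i) out(i, m) = modes[m][i];
  for (int i = 0; i < n; ++i) out(i, nm) = res[i];
  return out;
}

// Ensemble EMD: noise realizations supplied by the caller (one column per
// ensemble member, already scaled). Modes are averaged slot-wise across the
// ensemble; realizations yielding fewer modes contribute zeros there (their
// remaining signal stays in the residual slot).
// [[Rcpp::export(name = ".eemd_cpp")]]
NumericMatrix eemd_cpp(NumericVector x, NumericMatrix noise,
                       int nsift, int max_imf) {
  const int n = x.size(), ens = noise.ncol();
  NumericMatrix acc(n, max_imf + 1);
  std::vector<double> xi(n), res;
  std::vector<std::vector<double> > modes(max_imf);
  for (int e = 0; e < ens; ++e) {
    for (int i = 0; i < n; ++i) xi[i] = x[i] + noise(i, e);
    for (int m = 0; m < max_imf; ++m) modes[m].clear();
    int nm = emd_one(xi, nsift, max_imf, modes, res);
    for (int m = 0; m < nm; ++m)
      for (int i = 0; i < n; ++i) acc(i, m) += modes[m][i];
    for (int i = 0; i < n; ++i) acc(i, max_imf) += res[i];
  }
  for (int j = 0; j <= max_imf; ++j)
    for (int i = 0; i < n; ++i) acc(i, j) /= ens;
  return acc;
}
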