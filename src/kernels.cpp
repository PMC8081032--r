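#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Accumulate a linearly interpolated wavelet into buf.
// Sample idx = i0 + i receives w evaluated at fractional position (i - f),
// where s0 = i0 + f is the (possibly negative) fractional start sample.
static inline void add_wavelet(double *buf, int nbuf, double s0,
                               const double *w, int L, double amp) {
  int i0 = (int)std::floor(s0);
  double f = s0 - (double)i0;
  for (int i = 0; i <= L; ++i) {
    int idx = i0 + i;
    if (idx < 0 || idx >= nbuf) continue;
    double v = 0.0;
    if (i < L) v += (1.0 - f) * w[i];
    if (i > 0) v += f * w[i - 1];
    buf[idx] += amp * v;
  }
}

// Forward RF model: superposition of point-scatterer echoes.
// For each scatterer k the transmit arrivals from the active elements are
// accumulated into a short waveform on the RF sample grid, which is then
// shifted (linear interpolation) onto every receive channel. Equivalent to
// the direct triple superposition of interpolated wavelets.
// [[Rcpp::export]]
NumericMatrix rf_forward_cpp(NumericVector element_x, NumericVector tx_delays,
                             IntegerVector tx_active, NumericVector sx,
                             NumericVector sz, NumericVector amp,
                             NumericVector wavelet, double wavelet_center,
                             double fs, double t0, int n_samples, double c,
                             int spreading, int directivity) {
  const int ne = element_x.size();
  const int nk = sx.size();
  const int L = wavelet.size();
  const int na = tx_active.size();
  NumericMatrix out(n_samples, ne);
  if (nk == 0 || na == 0) return out;
  const double invc = 1.0 / c;
  std::vector<double> d(ne), invd(ne), cosang(ne), tA(na), gA(na);
  std::vector<double> g; // per-scatterer transmit waveform buffer
  double *outp = REAL(out);
  const double *w = REAL(wavelet);

  for (int k = 0; k < nk; ++k) {
    for (int e = 0; e < ne; ++e) {
      double dx = sx[k] - element_x[e];
      double dd = std::sqrt(dx * dx + sz[k] * sz[k]);
      if (dd < 1e-9) dd = 1e-9;
      d[e] = dd;
      invd[e] = 1.0 / dd;
      cosang[e] = sz[k] / dd;
    }
    double tmin = R_PosInf, tmax = R_NegInf;
    for (int a = 0; a < na; ++a) {
      int e = tx_active[a]; // 0-based
      tA[a] = tx_delays[e] + d[e] * invc;
      double ga = 1.0;
      if (spreading) ga *= invd[e];
      if (directivity) ga *= cosang[e];
      gA[a] = ga;
      if (tA[a] < tmin) tmin = tA[a];
      if (tA[a] > tmax) tmax = tA[a];
    }
    int M = (int)std::ceil((tmax - tmin) * fs) + L + 3;
    g.assign((size_t)M, 0.0);
    for (int a = 0; a < na; ++a)
      add_wavelet(g.data(), M, (tA[a] - tmin) * fs, w, L, gA[a]);

    // receive: channel j gets amp_k * g shifted by d_kj/c
    double tg0 = tmin - wavelet_center; // time of g[0]
    for (int j = 0; j < ne; ++j) {
      double b = amp[k];
      if (spreading) b *= invd[j];
      if (directivity) b *= cosang[j];
      double s = (tg0 + d[j] * invc - t0) * fs;
      int i0 = (int)std::floor(s);
      double f = s - (double)i0;
      double *oc = outp + (size_t)j * n_samples;
      for (int m = 0; m <= M; ++m) {
        int idx = i0 + m;
        if (idx < 0 || idx >= n_samples) continue;
        double v = 0.0;
        if (m < M) v += (1.0 - f) * g[m];
        if (m > 0) v += f * g[m - 1];
        oc[idx] += b * v;
      }
    }
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Delay-and-sum with dynamic receive aperture, Hanning apodization over the
// nominal subaperture width, and coherence factor per image point.
// tau_tx(iz, ix) holds the transmit part of the delay law; the receive part
// sqrt(z^2 + (x_i - x_c)^2)/c is added here. Linear interpolation in time.
// [[Rcpp::export]]
List das_core_cpp(NumericMatrix rf, double fs, double t0,
                  NumericVector element_x, NumericVector x_grid,
                  NumericVector z_grid, NumericMatrix tau_tx, double c,
                  double f_number, int apod_hann, int cf_apodized,
                  int return_samples) {
  const int nt = rf.nrow(), ne = rf.ncol();
  const int nx = x_grid.size(), nz = z_grid.size();
  NumericMatrix y(nz, nx), cf(nz, nx);
  IntegerMatrix nused(nz, nx);
  NumericVector samples;
  double *sampp = NULL;
  if (return_samples) {
    samples = NumericVector((size_t)nz * nx * ne, NA_REAL);
    sampp = REAL(samples);
  }
  const double invc = 1.0 / c;
  const double *rfp = REAL(rf);
  long oob = 0;

  for (int ix = 0; ix < nx; ++ix) {
    double xc = x_grid[ix];
    for (int iz = 0; iz < nz; ++iz) {
      double z = z_grid[iz];
      double a = z / (2.0 * f_number); // subaperture half-width
      // elements with |x_e - xc| <= a (element_x ascending)
      int lo = (int)(std::lower_bound(element_x.begin(), element_x.end(),
                                      xc - a) - element_x.begin());
      int hi = (int)(std::upper_bound(element_x.begin(), element_x.end(),
                                      xc + a) - element_x.begin()) - 1;
      double ysum = 0.0, csum = 0.0, esum = 0.0;
      int N = 0;
      double taut = tau_tx(iz, ix);
      for (int e = lo; e <= hi; ++e) {
        double dx = element_x[e] - xc;
        double wgt = 1.0;
        if (apod_hann)
          wgt = (a > 0.0) ? 0.5 * (1.0 + std::cos(M_PI * dx / a)) : 1.0;
        double tau = taut + std::sqrt(z * z + dx * dx) * invc;
        double s = (tau - t0) * fs;
        int i0 = (int)std::floor(s);
        double v;
        if (i0 < 0 || i0 + 1 >= nt) {
          v = 0.0;
          ++oob;
        } else {
          double f = s - (double)i0;
          const double *col = rfp + (size_t)e * nt;
          v = (1.0 - f) * col[i0] + f * col[i0 + 1];
        }
        double sv = wgt * v;
        ysum += sv;
        double q = cf_apodized ? sv : v;
        csum += q;
        esum += q * q;
        ++N;
        if (sampp)
          sampp[(size_t)iz + (size_t)nz * ((size_t)ix + (size_t)nx * e)] = q;
      }
      y(iz, ix) = ysum;
      nused(iz, ix) = N;
      double cfv = 0.0;
      if (esum > 0.0 && N > 0) {
        cfv = (csum * csum) / ((double)N * esum);
        if (cfv > 1.0) cfv = 1.0; // guard fp round-off
        if (cfv < 0.0) cfv = 0.0;
      }
      cf(iz, ix) = cfv;
    }
    Rcpp::checkUserInterrupt();
  }
  List res = List::create(_["y"] = y, _["cf"] = cf, _["n_used"] = nused,
                          _["n_oob"] = (double)oob);
  if (return_samples) {
    samples.attr("dim") = IntegerVector::create(nz, nx, ne);
    res["samples"] = samples;
  }
  return res;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection; valid for |overhang| < n
  if (i < 0) i = -1 - i;
  if (i >= n) i = 2 * n - 1 - i;
  return i;
}

// Separable moving-average filter with symmetric-reflection padding.
// [[Rcpp::export]]
NumericMatrix movavg_reflect_cpp(NumericMatrix x, int kz, int kx) {
  const int nz = x.nrow(), nx = x.ncol();
  const int hz = kz / 2, hx = kx / 2;
  NumericMatrix tmp(nz, nx), out(nz, nx);
  // axial pass
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) {
      double s = 0.0;
      for (int u = -hz; u <= hz; ++u) s += x(reflect_idx(i + u, nz), j);
      tmp(i, j) = s / (double)kz;
    }
  // lateral pass
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) {
      double s = 0.0;
      for (int u = -hx; u <= hx; ++u) s += tmp(i, reflect_idx(j + u, nx));
      out(i, j) = s / (double)kx;
    }
  return out;
}

// 2-D median filter (odd kernel sizes) with symmetric-reflection padding.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int kz, int kx) {
  const int nz = x.nrow(), nx = x.ncol();
  const int hz = kz / 2, hx = kx / 2;
  NumericMatrix out(nz, nx);
  std::vector<double> win((size_t)kz * kx);
  const int mid = (kz * kx) / 2;
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < nz; ++i) {
      int m = 0;
      for (int u = -hx; u <= hx; ++u) {
        int jj = reflect_idx(j + u, nx);
        for (int v = -hz; v <= hz; ++v)
          win[m++] = x(reflect_idx(i + v, nz), jj);
      }
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      out(i, j) = win[mid];
    }
    if ((j & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
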