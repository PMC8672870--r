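#include <Rcpp.h>
#include <complex>
#include <cmath>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

// Rayleigh-Sommerfeld summation: p(obs_j) = sum_i amp_i * exp(-(ik + a) r_ij) / r_ij
// src: n x 3 (m), obs: m x 3 (m), amp: complex n (drive x jwrho dA / 2pi folded in).
// Observation points closer than r_min to any sub-source are flagged (their
// contribution from that source is skipped); the count is returned as an attribute.
// [[Rcpp::export(name = ".rs_sum")]]
ComplexVector rs_sum(NumericMatrix src, ComplexVector amp, NumericMatrix obs,
                     double k, double alpha, double r_min) {
  const int n = src.nrow(), m = obs.nrow();
  ComplexVector out(m);
  int skipped = 0;
  std::vector<double> sx(n), sy(n), sz(n), ar(n), ai(n);
  for (int i = 0; i < n; ++i) {
    sx[i] = src(i, 0); sy[i] = src(i, 1); sz[i] = src(i, 2);
    ar[i] = amp[i].r; ai[i] = amp[i].i;
  }
  std::vector<double> outr(m), outi(m);
  const double *ox_p = &obs(0, 0), *oy_p = &obs(0, 1), *oz_p = &obs(0, 2);
  const bool lossless = (alpha == 0.0);
#ifdef _OPENMP
#pragma omp parallel for schedule(static) reduction(+:skipped)
#endif
  for (int j = 0; j < m; ++j) {
    const double ox = ox_p[j], oy = oy_p[j], oz = oz_p[j];
    double accr = 0.0, acci = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = ox - sx[i], dy = oy - sy[i], dz = oz - sz[i];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < r_min) { ++skipped; continue; }
      const double decay = (lossless ? 1.0 : std::exp(-alpha * r)) / r;
      const double ph = -k * r;
      const double c = decay * std::cos(ph), s = decay * std::sin(ph);
      accr += ar[i] * c - ai[i] * s;
      acci += ar[i] * s + ai[i] * c;
    }
    outr[j] = accr;
    outi[j] = acci;
  }
  for (int j = 0; j < m; ++j) { out[j].r = outr[j]; out[j].i = outi[j]; }
  out.attr("skipped") = skipped;
  return out;
}
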