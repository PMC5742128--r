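// Compiled core of the myelinated-axon cable model: implicit-Euler time
// stepping of the nodal membrane equations with CRRSS (fast Na + leak)
// kinetics. The tridiagonal implicit system is constant over time, so it is
// factorized once (Thomas algorithm) and reused every step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double waveform_value(const std::vector<double>& edges,
                                    const NumericVector& amps, double t) {
  if (t < 0.0 || t >= edges.back()) return 0.0;
  for (size_t i = 1; i < edges.size(); ++i)
    if (t < edges[i]) return amps[i - 1];
  return 0.0;
}

// returns 1 if a spike occurred, 0 if not, -1 on numerical instability
// [[Rcpp::export(name = ".cable_spike")]]
int cable_spike(NumericVector u, NumericVector durations, NumericVector amps,
                double amplitude, double dt, double tail,
                double c_node, double g_axial, double area,
                double g_na, double g_l, double e_na, double e_l,
                double temp_factor, double v_spike_rel) {
  const int N = u.size();
  std::vector<double> edges(durations.size() + 1, 0.0);
  for (int i = 0; i < durations.size(); ++i)
    edges[i + 1] = edges[i] + durations[i];
  const double support = edges.back();
  const int steps = (int)std::ceil((support + tail) / dt);

  // tridiagonal A = (C/dt) I - Ga * L, L = sealed-end second difference
  std::vector<double> diag(N), cp(N), v(N, 0.0), m(N), h(N), ve(N, 0.0);
  const double off = -g_axial;
  for (int i = 0; i < N; ++i) {
    double li = (i == 0 || i == N - 1) ? -1.0 : -2.0;
    diag[i] = c_node / dt - g_axial * li;
  }
  // Thomas factorization (constant matrix)
  cp[0] = off / diag[0];
  for (int i = 1; i < N; ++i)
    cp[i] = off / (diag[i] - off * cp[i - 1]);

  // resting gate states (v = 0 relative to rest)
  {
    double am = 1e3 * 97.0 / (1.0 + std::exp(31.0 / 5.3));
    double bm = am / std::exp(-23.8 / 4.17);
    double bh = 1e3 * 15.6 / (1.0 + std::exp(24.0 / 10.0));
    double ah = bh / std::exp(-5.5 / 5.0);
    for (int i = 0; i < N; ++i) {
      m[i] = am / (am + bm);
      h[i] = ah / (ah + bh);
    }
  }

  std::vector<double> rhs(N);
  for (int s = 1; s <= steps; ++s) {
    const double t1 = s * dt;
    const double scale = amplitude * waveform_value(edges, amps, t1);
    for (int i = 0; i < N; ++i) ve[i] = scale * u[i];
    for (int i = 0; i < N; ++i) {
      const double vm = v[i] * 1e3;
      double am = 1e3 * (97.0 + 0.363 * vm) / (1.0 + std::exp((31.0 - vm) / 5.3));
      double bm = am / std::exp((vm - 23.8) / 4.17);
      double bh = 1e3 * 15.6 / (1.0 + std::exp((24.0 - vm) / 10.0));
      double ah = bh / std::exp((vm - 5.5) / 5.0);
      am *= temp_factor; bm *= temp_factor;
      ah *= temp_factor; bh *= temp_factor;
      const double sm = am + bm, sh = ah + bh;
      m[i] = am / sm + (m[i] - am / sm) * std::exp(-dt * sm);
      h[i] = ah / sh + (h[i] - ah / sh) * std::exp(-dt * sh);
      const double m3 = m[i] * m[i] * m[i];
      const double i_ion = area * (g_na * m3 * h[i] * (v[i] - e_na) +
                                   g_l * (v[i] - e_l));
      // sealed-end second difference of the extracellular potential
      double d2;
      if (i == 0) d2 = ve[1] - ve[0];
      else if (i == N - 1) d2 = ve[N - 2] - ve[N - 1];
      else d2 = ve[i - 1] - 2.0 * ve[i] + ve[i + 1];
      rhs[i] = (c_node / dt) * v[i] - i_ion + g_axial * d2;
    }
    // Thomas solve A v = rhs
    double dprime = rhs[0] / diag[0];
    v[0] = dprime;  // temporary: store forward sweep in v
    for (int i = 1; i < N; ++i)
      v[i] = (rhs[i] - off * v[i - 1]) / (diag[i] - off * cp[i - 1]);
    for (int i = N - 2; i >= 0; --i)
      v[i] -= cp[i] * v[i + 1];

    double vmax = 0.0;
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1.0) return -1;
      if (v[i] > vmax) vmax = v[i];
    }
    if (vmax >= v_spike_rel) return 1;
  }
  return 0;
}
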