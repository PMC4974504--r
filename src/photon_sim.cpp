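#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "sim_rng.h"

using namespace Rcpp;

// Brownian-dynamics photon-stream simulator.
//
// n_mol molecules diffuse in a periodic box (half widths `box_half`,
// micrometres) and interconvert between two conformational states
// (closed = 0 -> open = 1 at k_open; back at k_close).  Detection is
// weighted by a 3D Gaussian focus exp(-2 r_xy^2/mu^2 - 2 z^2/(p mu)^2);
// emission is Poisson with per-channel, per-state centre brightness
// (counts/s), modulated by independent per-dye triplet telegraph
// processes with stationary dark fractions f_trip[ch] and correlation
// times tau_T[ch] (donor, acceptor).  Donor
// photons leak to the acceptor channel with probability beta_x;
// homogeneous Poisson background is added per channel.
//
// Returned photon times are seconds, channels are 1 = donor,
// 2 = acceptor.  Conformational transition events (time, molecule,
// new state) are recorded when record_transitions is true.
// [[Rcpp::export]]
List simulate_photons_cpp(int n_mol, NumericVector box_half, double D,
                          double mu, double p, NumericMatrix brightness,
                          double k_open, double k_close,
                          NumericVector f_trip, NumericVector tau_T,
                          double beta_x, NumericVector background,
                          double dt, double duration, double seed,
                          bool record_transitions) {
  const double Lx = box_half[0], Ly = box_half[1], Lz = box_half[2];
  const double z0 = p * mu;
  const double inv_mu2 = 2.0 / (mu * mu), inv_z02 = 2.0 / (z0 * z0);
  const double sig = std::sqrt(2.0 * D * dt);
  const long n_steps = (long)std::floor(duration / dt);
  const double ksum = k_open + k_close;
  const double p_open = ksum > 0 ? k_open / ksum : 0.0;
  // per-dye triplet telegraph rates from stationary dark fraction +
  // correlation time (independent donor/acceptor blinking)
  double k_bd[2], k_db[2];
  for (int c = 0; c < 2; ++c) {
    k_bd[c] = f_trip[c] > 0 ? f_trip[c] / tau_T[c] : 0.0;  // bright->dark
    k_db[c] = f_trip[c] > 0 ? (1.0 - f_trip[c]) / tau_T[c] : 0.0;
  }

  SimRng rng((std::uint64_t)seed);

  std::vector<double> ph_t;
  std::vector<unsigned char> ph_c;
  std::vector<double> tr_t;
  std::vector<int> tr_mol, tr_state;
  ph_t.reserve(1 << 16);
  ph_c.reserve(1 << 16);

  const double inf = std::numeric_limits<double>::infinity();

  for (int m = 0; m < n_mol; ++m) {
    double x = (2.0 * rng.runif() - 1.0) * Lx;
    double y = (2.0 * rng.runif() - 1.0) * Ly;
    double z = (2.0 * rng.runif() - 1.0) * Lz;
    int state = (ksum > 0 && rng.runif() < p_open) ? 1 : 0;
    bool dark[2];
    double next_conf = inf, next_trip[2] = {inf, inf};
    if (ksum > 0)
      next_conf = rng.rexp(state == 1 ? k_close : k_open);
    for (int c = 0; c < 2; ++c) {
      dark[c] = (f_trip[c] > 0) && (rng.runif() < f_trip[c]);
      if (f_trip[c] > 0)
        next_trip[c] = rng.rexp(dark[c] ? k_db[c] : k_bd[c]);
    }

    for (long i = 0; i < n_steps; ++i) {
      const double t = i * dt;
      while (next_conf <= t) {
        state = 1 - state;
        if (record_transitions) {
          tr_t.push_back(next_conf);
          tr_mol.push_back(m + 1);
          tr_state.push_back(state);
        }
        next_conf += rng.rexp(state == 1 ? k_close : k_open);
      }
      for (int c = 0; c < 2; ++c) {
        while (next_trip[c] <= t) {
          dark[c] = !dark[c];
          next_trip[c] += rng.rexp(dark[c] ? k_db[c] : k_bd[c]);
        }
      }
      x += sig * rng.rnorm();
      y += sig * rng.rnorm();
      z += sig * rng.rnorm();
      if (x > Lx) x -= 2.0 * Lx; else if (x < -Lx) x += 2.0 * Lx;
      if (y > Ly) y -= 2.0 * Ly; else if (y < -Ly) y += 2.0 * Ly;
      if (z > Lz) z -= 2.0 * Lz; else if (z < -Lz) z += 2.0 * Lz;
      const double expo = (x * x + y * y) * inv_mu2 + z * z * inv_z02;
      if (expo > 16.0) continue;  // w < 1.2e-7: negligible emission
      const double w = std::exp(-expo);
      for (int ch = 0; ch < 2; ++ch) {
        if (dark[ch]) continue;
        const double lam = brightness(state, ch) * w * dt;
        if (lam <= 0) continue;
        int n;
        if (lam < 1e-4) n = (rng.runif() < lam) ? 1 : 0;
        else n = rng.rpois_small(lam);
        for (int k = 0; k < n; ++k) {
          double tt = t + rng.runif() * dt;
          int out_ch = ch;
          if (ch == 0 && beta_x > 0 && rng.runif() < beta_x) out_ch = 1;
          ph_t.push_back(tt);
          ph_c.push_back((unsigned char)(out_ch + 1));
        }
      }
    }
  }

  // background: homogeneous Poisson process per channel
  for (int ch = 0; ch < 2; ++ch) {
    const double rate = background[ch];
    if (rate <= 0) continue;
    double t = rng.rexp(rate);
    while (t < duration) {
      ph_t.push_back(t);
      ph_c.push_back((unsigned char)(ch + 1));
      t += rng.rexp(rate);
    }
  }

  // sort photons by arrival time
  const std::size_t n_ph = ph_t.size();
  std::vector<std::size_t> idx(n_ph);
  for (std::size_t i = 0; i < n_ph; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](std::size_t a, std::size_t b) {
                     return ph_t[a] < ph_t[b];
                   });
  NumericVector out_t(n_ph);
  IntegerVector out_c(n_ph);
  for (std::size_t i = 0; i < n_ph; ++i) {
    out_t[i] = ph_t[idx[i]];
    out_c[i] = ph_c[idx[i]];
  }

  List trans = List::create(Named("time") = wrap(tr_t),
                            Named("molecule") = wrap(tr_mol),
                            Named("state") = wrap(tr_state));
  return List::create(Named("times") = out_t,
                      Named("channel") = out_c,
                      Named("transitions") = trans);
}
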