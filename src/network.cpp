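#include "fprate_common.h"
#include <random>
using namespace Rcpp;

// Polar (Marsaglia) method for standard normals on top of mt19937_64,
// keeping the simulator reproducible for a given integer seed.
struct NormalGen {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;
  double spare;
  bool has_spare;
  NormalGen(uint64_t seed) : rng(seed), unif(-1.0, 1.0), spare(0), has_spare(false) {}
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = unif(rng); v = unif(rng);
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

// Euler-Maruyama simulation of N sparsely coupled aEIF neurons with delayed
// pulse coupling.  Each neuron receives K presynaptic partners drawn
// uniformly without replacement (and without self-connection); each
// connection's delay is sampled once from the delay distribution and rounded
// to the step size; a presynaptic spike delivers a voltage jump J to the
// target after its delay.  mu_ext / sig_ext are the external input mean
// (mV/ms) and standard deviation (mV ms^-1/2) sampled on the step grid.
// delay_kind: 0 = none, 1 = exponential(tau_d), 2 = identical(d_fixed).
// [[Rcpp::export]]
List cpp_simulate_network(int N, int n_steps, double dt,
                          NumericVector mu_ext, NumericVector sig_ext,
                          NumericVector V0,
                          double Cap, double gL, double EL, double DT,
                          double VT, double Vs, double Vr, double Tref,
                          double a, double b, double tau_w, double E_w,
                          int K, double J, int delay_kind, double tau_d,
                          double d_fixed, double seed, int rec_every,
                          bool want_raster) {
  NormalGen gen((uint64_t)seed);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> w(N, 0.0);
  std::vector<int> refr(N, 0);
  int n_ref_steps = (int)std::lround(Tref / dt);

  // connectivity: out[j] lists (target, delay slot) for presynaptic neuron j
  std::vector<std::vector<std::pair<int, int> > > out;
  int Lbuf = 1;
  if (K > 0) {
    if (K >= N) stop("in-degree K must be smaller than N");
    int max_slot;
    if (delay_kind == 1) max_slot = std::max(1, (int)std::ceil(12.0 * tau_d / dt));
    else if (delay_kind == 2) max_slot = std::max(1, (int)std::lround(d_fixed / dt));
    else max_slot = 1;
    Lbuf = max_slot + 2;
    out.assign(N, std::vector<std::pair<int, int> >());
    std::uniform_real_distribution<double> u01(0.0, 1.0);
    std::vector<int> pool(N);
    for (int i = 0; i < N; ++i) {
      // K distinct presynaptic partners != i (partial Fisher-Yates)
      for (int j = 0; j < N; ++j) pool[j] = j;
      pool[i] = N - 1; pool[N - 1] = i; // move self to the end, never drawn
      int avail = N - 1;
      for (int k = 0; k < K; ++k) {
        int idx = (int)(u01(gen.rng) * avail);
        if (idx >= avail) idx = avail - 1;
        int j = pool[idx];
        pool[idx] = pool[avail - 1];
        --avail;
        int slot;
        if (delay_kind == 1) {
          double d = -tau_d * std::log(1.0 - u01(gen.rng));
          slot = (int)std::lround(d / dt);
          if (slot < 1) slot = 1;
          if (slot > max_slot) slot = max_slot;
        } else if (delay_kind == 2) {
          slot = std::max(1, (int)std::lround(d_fixed / dt));
        } else slot = 1;
        out[j].push_back(std::make_pair(i, slot));
      }
    }
  }
  std::vector<std::vector<double> > buf;
  if (K > 0) buf.assign(Lbuf, std::vector<double>(N, 0.0));

  // lookup table for the exponential membrane drift
  double Vtab0 = Vr - 80.0;
  double dtab = 0.01;
  int ntab = (int)std::ceil((Vs - Vtab0) / dtab) + 2;
  std::vector<double> gtab(ntab);
  for (int i = 0; i < ntab; ++i)
    gtab[i] = eif_drift(Vtab0 + i * dtab, Cap, gL, EL, DT, VT);
  auto drift = [&](double v) -> double {
    if (v <= Vtab0) return -gL * (v - EL) / Cap; // exp current negligible
    double x = (v - Vtab0) / dtab;
    int i = (int)x;
    if (i >= ntab - 1) i = ntab - 2;
    double f = x - i;
    return gtab[i] * (1 - f) + gtab[i + 1] * f;
  };

  int n_rec = n_steps / rec_every;
  NumericVector count_bin(n_rec), meanV_rec(n_rec), meanw_rec(n_rec);
  std::vector<double> sp_t;
  std::vector<int> sp_i;
  double sqdt = std::sqrt(dt);
  long total_spikes = 0;
  double meanV_last = 0.0;
  long bin_count = 0;

  for (int step = 0; step < n_steps; ++step) {
    double mu = mu_ext[step], sg = sig_ext[step];
    int slot_now = step % Lbuf;
    double *pend = (K > 0) ? buf[slot_now].data() : (double *)0;
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { refr[i]--; if (pend) pend[i] = 0.0; continue; }
      double v = V[i];
      if (pend) { v += pend[i]; pend[i] = 0.0; }
      double wi = w[i];
      double vnew = v + dt * (drift(v) + (-wi / Cap) + mu) + sqdt * sg * gen();
      w[i] = wi + dt * (a * (v - E_w) - wi) / tau_w;
      if (vnew >= Vs) {
        total_spikes++;
        bin_count++;
        if (want_raster) { sp_t.push_back((step + 1) * dt); sp_i.push_back(i + 1); }
        vnew = Vr;
        w[i] += b;
        refr[i] = n_ref_steps;
        if (K > 0) {
          const std::vector<std::pair<int, int> > &tg = out[i];
          for (size_t e = 0; e < tg.size(); ++e)
            buf[(step + tg[e].second) % Lbuf][tg[e].first] += J;
        }
      }
      V[i] = vnew;
    }
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      count_bin[k] = (double)bin_count;
      bin_count = 0;
      double sv = 0.0, sw = 0.0;
      int nn = 0;
      for (int i = 0; i < N; ++i) {
        sw += w[i];
        if (refr[i] == 0) { sv += V[i]; nn++; }
      }
      meanV_rec[k] = (nn > 0) ? sv / nn : meanV_last;
      meanV_last = meanV_rec[k];
      meanw_rec[k] = sw / N;
    }
  }
  List res = List::create(_["count_bin"] = count_bin,
                          _["mean_V"] = meanV_rec, _["mean_w"] = meanw_rec,
                          _["total_spikes"] = (double)total_spikes);
  if (want_raster) {
    res["spike_time"] = NumericVector(sp_t.begin(), sp_t.end());
    res["spike_id"] = IntegerVector(sp_i.begin(), sp_i.end());
  }
  return res;
}
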