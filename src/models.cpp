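#include "fprate_common.h"
using namespace Rcpp;

// Bilinear interpolation on the uniform (mu, sigma) quantity grid with
// clamping at the bounds (transient excursions of the total moments during
// stiff dynamics must not abort a run).
struct QGrid {
  double mu0, dmu, s0, ds;
  int nm, ns;
  QGrid(NumericVector mu, NumericVector sg) {
    mu0 = mu[0]; nm = mu.size();
    dmu = (nm > 1) ? (mu[nm - 1] - mu0) / (nm - 1) : 1.0;
    s0 = sg[0]; ns = sg.size();
    ds = (ns > 1) ? (sg[ns - 1] - s0) / (ns - 1) : 1.0;
  }
  // locate + weights
  void locate(double mu, double sg, int &i, int &j, double &fx, double &fy) const {
    double x = (mu - mu0) / dmu;
    if (x < 0) x = 0;
    if (x > nm - 1) x = nm - 1;
    i = (int)x; if (i > nm - 2) i = nm - 2;
    fx = x - i;
    double y = (sg - s0) / ds;
    if (y < 0) y = 0;
    if (y > ns - 1) y = ns - 1;
    j = (int)y; if (j > ns - 2) j = ns - 2;
    fy = y - j;
  }
  double val(const double *m, int i, int j, double fx, double fy) const {
    const double *c0 = m + (size_t)j * nm, *c1 = m + (size_t)(j + 1) * nm;
    return (1 - fy) * ((1 - fx) * c0[i] + fx * c0[i + 1]) +
           fy * ((1 - fx) * c1[i] + fx * c1[i + 1]);
  }
};

// linear interpolation of an input signal sampled at spacing sdt
static inline double sig_at(const double *x, int n, double sdt, double t) {
  double u = t / sdt;
  if (u <= 0) return x[0];
  int i = (int)u;
  if (i >= n - 1) return x[n - 1];
  double f = u - i;
  return x[i] * (1 - f) + x[i + 1] * f;
}

struct Shared {
  double K, J, a, b, tau_w, E_w, Cap, tau_d;
  int delay_kind; // 0 none, 1 exponential, 2 identical
};

// ---------------------------------------------------------------------------
// spec1: complex first-order rate equation  dr~/dt = lambda_1 (r~ - r_inf)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_spec1(NumericVector mu_grid, NumericVector sg_grid,
                   NumericMatrix r_inf, NumericMatrix V_inf,
                   NumericMatrix l1re, NumericMatrix l1im,
                   NumericVector mu_ext, NumericVector sig2_ext, double sdt,
                   double dt, int n_steps, List shared_par, int rec_every,
                   bool heun, double w0, double rd0) {
  QGrid g(mu_grid, sg_grid);
  Shared sp;
  sp.K = shared_par["K"]; sp.J = shared_par["J"]; sp.a = shared_par["a"];
  sp.b = shared_par["b"]; sp.tau_w = shared_par["tau_w"];
  sp.E_w = shared_par["E_w"]; sp.Cap = shared_par["C"];
  sp.tau_d = shared_par["tau_d"]; sp.delay_kind = shared_par["delay_kind"];
  int nsig = mu_ext.size();
  int n_d = (sp.delay_kind == 2) ? std::max(1, (int)std::lround((double)shared_par["d"] / dt)) : 0;
  std::vector<double> rbuf;
  if (sp.delay_kind == 2) rbuf.assign(n_steps + 1, 0.0);

  // state: re r~, im r~, w, rd
  double st[4];
  st[2] = w0; st[3] = rd0;
  // derivative evaluation
  double VinfC = 0.0;
  auto deriv = [&](const double *s, double t, double *ds) {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, t);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, t);
    double rd = s[3];
    double mu_syn = mu_e + sp.J * sp.K * rd;
    double sig2 = s2_e + sp.J * sp.J * sp.K * rd;
    double mu_tot = mu_syn - s[2] / sp.Cap;
    double sg = std::sqrt(sig2);
    int i, j; double fx, fy;
    g.locate(mu_tot, sg, i, j, fx, fy);
    double ri = g.val(r_inf.begin(), i, j, fx, fy);
    double Vi = g.val(V_inf.begin(), i, j, fx, fy);
    double lre = g.val(l1re.begin(), i, j, fx, fy);
    double lim = g.val(l1im.begin(), i, j, fx, fy);
    VinfC = Vi;
    double dre = lre * (s[0] - ri) - lim * s[1];
    double dim = lre * s[1] + lim * (s[0] - ri);
    double r_out = std::max(s[0], 0.0);
    ds[0] = dre; ds[1] = dim;
    ds[2] = (sp.a * (Vi - sp.E_w) - s[2]) / sp.tau_w + sp.b * r_out;
    ds[3] = (sp.delay_kind == 1) ? (r_out - rd) / sp.tau_d : 0.0;
  };
  // initialize r~ to the stationary rate at the initial total moments
  {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, 0.0);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, 0.0);
    double mu_tot = mu_e + sp.J * sp.K * rd0 - w0 / sp.Cap;
    double sg = std::sqrt(s2_e + sp.J * sp.J * sp.K * rd0);
    int i, j; double fx, fy;
    g.locate(mu_tot, sg, i, j, fx, fy);
    st[0] = g.val(r_inf.begin(), i, j, fx, fy);
    st[1] = 0.0;
  }
  int n_rec = n_steps / rec_every;
  NumericVector rate(n_rec), wv(n_rec), rdv(n_rec), Vv(n_rec);
  double acc = 0.0;
  double ds1[4], ds2[4], pred[4];
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    deriv(st, t, ds1);
    if (heun) {
      for (int q = 0; q < 4; ++q) pred[q] = st[q] + dt * ds1[q];
      deriv(pred, t + dt, ds2);
      for (int q = 0; q < 4; ++q) st[q] += 0.5 * dt * (ds1[q] + ds2[q]);
    } else {
      for (int q = 0; q < 4; ++q) st[q] += dt * ds1[q];
    }
    double r_out = std::max(st[0], 0.0);
    if (sp.delay_kind == 2) {
      rbuf[step + 1] = r_out;
      st[3] = (step + 1 - n_d >= 0) ? rbuf[step + 1 - n_d] : 0.0;
    } else if (sp.delay_kind == 0) st[3] = r_out;
    acc += r_out;
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      rate[k] = acc / rec_every; acc = 0.0;
      wv[k] = st[2]; rdv[k] = st[3]; Vv[k] = VinfC;
    }
  }
  return List::create(_["rate"] = rate, _["mean_w"] = wv, _["r_d"] = rdv,
                      _["mean_V"] = Vv);
}

// ---------------------------------------------------------------------------
// spec2: real second-order rate ODE with lumped spectral coefficients
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_spec2(NumericVector mu_grid, NumericVector sg_grid,
                   NumericMatrix r_inf, NumericMatrix V_inf,
                   NumericMatrix l1re, NumericMatrix l1im,
                   NumericMatrix l2re, NumericMatrix l2im,
                   NumericMatrix Mq, NumericMatrix Sq,
                   NumericMatrix Fmu, NumericMatrix Fs2,
                   NumericMatrix dmuV, NumericMatrix ds2V,
                   NumericVector mu_ext, NumericVector sig2_ext,
                   NumericVector mu_dot, NumericVector mu_ddot,
                   NumericVector s2_dot, NumericVector s2_ddot,
                   double sdt, double dt, int n_steps, List shared_par,
                   int rec_every, bool heun, double w0, double rd0) {
  QGrid g(mu_grid, sg_grid);
  Shared sp;
  sp.K = shared_par["K"]; sp.J = shared_par["J"]; sp.a = shared_par["a"];
  sp.b = shared_par["b"]; sp.tau_w = shared_par["tau_w"];
  sp.E_w = shared_par["E_w"]; sp.Cap = shared_par["C"];
  sp.tau_d = shared_par["tau_d"]; sp.delay_kind = shared_par["delay_kind"];
  int nsig = mu_ext.size();
  double tau_d = (sp.delay_kind == 1) ? sp.tau_d : 1.0; // coupling terms carry K
  double KJ = sp.K * sp.J, KJ2 = sp.K * sp.J * sp.J;

  // state: r, y = dr/dt, w, rd
  double st[4];
  st[1] = 0.0; st[2] = w0; st[3] = rd0;
  double VinfC = 0.0;
  auto deriv = [&](const double *s, double t, double *ds) {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, t);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, t);
    double mud = sig_at(mu_dot.begin(), nsig, sdt, t);
    double mudd = sig_at(mu_ddot.begin(), nsig, sdt, t);
    double s2d = sig_at(s2_dot.begin(), nsig, sdt, t);
    double s2dd = sig_at(s2_ddot.begin(), nsig, sdt, t);
    double rd = s[3];
    double mu_syn = mu_e + KJ * rd;
    double sig2 = s2_e + KJ2 * rd;
    double mu_tot = mu_syn - s[2] / sp.Cap;
    double sg = std::sqrt(sig2);
    int i, j; double fx, fy;
    g.locate(mu_tot, sg, i, j, fx, fy);
    double ri = g.val(r_inf.begin(), i, j, fx, fy);
    double Vi = g.val(V_inf.begin(), i, j, fx, fy);
    cplx l1(g.val(l1re.begin(), i, j, fx, fy), g.val(l1im.begin(), i, j, fx, fy));
    cplx l2(g.val(l2re.begin(), i, j, fx, fy), g.val(l2im.begin(), i, j, fx, fy));
    double M = g.val(Mq.begin(), i, j, fx, fy);
    double S = g.val(Sq.begin(), i, j, fx, fy);
    double FM = g.val(Fmu.begin(), i, j, fx, fy);
    double FS = g.val(Fs2.begin(), i, j, fx, fy);
    double dV1 = g.val(dmuV.begin(), i, j, fx, fy);
    double dV2 = g.val(ds2V.begin(), i, j, fx, fy);
    VinfC = Vi;
    double D = (1.0 / (l1 * l2)).real();
    double T = (1.0 / l1 + 1.0 / l2).real();
    double Hmu = T * M + D * M * sp.a * dV1 / (sp.tau_w * sp.Cap) - D * FM;
    double Hs2 = T * S + D * M * sp.a * dV2 / (sp.tau_w * sp.Cap) - D * FS;
    double R = D * M * KJ + D * S * KJ2;
    double b2 = D;
    double b1 = -T + D * M * sp.b / sp.Cap - R / tau_d;
    double b0 = -D * M * sp.b / (sp.tau_w * sp.Cap) - sp.b / sp.Cap * Hmu +
                (KJ * Hmu + KJ2 * Hs2) / tau_d + R / (tau_d * tau_d);
    double W = sp.a * (Vi - sp.E_w) - s[2];
    double bc = rd * (-(KJ * Hmu + KJ2 * Hs2) / tau_d - R / (tau_d * tau_d)) -
                (mudd + W / (sp.tau_w * sp.tau_w * sp.Cap)) * D * M -
                s2dd * D * S +
                (mud - W / (sp.tau_w * sp.Cap)) * Hmu + s2d * Hs2;
    ds[0] = s[1];
    ds[1] = (ri - s[0] - bc - b0 * s[0] - b1 * s[1]) / b2;
    double r_out = std::max(s[0], 0.0);
    ds[2] = (W + 0.0) / sp.tau_w + sp.b * r_out; // W already holds a(V-Ew)-w
    ds[3] = (sp.delay_kind == 1) ? (r_out - rd) / sp.tau_d : 0.0;
  };
  {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, 0.0);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, 0.0);
    double mu_tot = mu_e + KJ * rd0 - w0 / sp.Cap;
    double sg = std::sqrt(s2_e + KJ2 * rd0);
    int i, j; double fx, fy;
    g.locate(mu_tot, sg, i, j, fx, fy);
    st[0] = g.val(r_inf.begin(), i, j, fx, fy);
  }
  int n_rec = n_steps / rec_every;
  NumericVector rate(n_rec), wv(n_rec), rdv(n_rec), Vv(n_rec);
  double acc = 0.0;
  int n_d = (sp.delay_kind == 2) ? std::max(1, (int)std::lround((double)shared_par["d"] / dt)) : 0;
  std::vector<double> rbuf;
  if (sp.delay_kind == 2) rbuf.assign(n_steps + 1, 0.0);
  double ds1[4], ds2[4], pred[4];
  long n_clamped = 0;
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    deriv(st, t, ds1);
    if (heun) {
      for (int q = 0; q < 4; ++q) pred[q] = st[q] + dt * ds1[q];
      if (pred[0] < 0) { pred[0] = 0; pred[1] = 0; }
      deriv(pred, t + dt, ds2);
      for (int q = 0; q < 4; ++q) st[q] += 0.5 * dt * (ds1[q] + ds2[q]);
    } else {
      for (int q = 0; q < 4; ++q) st[q] += dt * ds1[q];
    }
    if (st[0] < 0) { st[0] = 0.0; st[1] = 0.0; n_clamped++; }
    double r_out = st[0];
    if (sp.delay_kind == 2) {
      rbuf[step + 1] = r_out;
      st[3] = (step + 1 - n_d >= 0) ? rbuf[step + 1 - n_d] : 0.0;
    } else if (sp.delay_kind == 0) st[3] = r_out;
    acc += r_out;
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      rate[k] = acc / rec_every; acc = 0.0;
      wv[k] = st[2]; rdv[k] = st[3]; Vv[k] = VinfC;
    }
  }
  return List::create(_["rate"] = rate, _["mean_w"] = wv, _["r_d"] = rdv,
                      _["mean_V"] = Vv, _["n_clamped"] = (double)n_clamped);
}

// ---------------------------------------------------------------------------
// LN_exp: first-order filters for mu and sigma, static nonlinearity r_inf
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_lnexp(NumericVector mu_grid, NumericVector sg_grid,
                   NumericMatrix r_inf, NumericMatrix V_inf,
                   NumericMatrix tau_mu, NumericMatrix tau_sg,
                   NumericVector mu_ext, NumericVector sig2_ext, double sdt,
                   double dt, int n_steps, List shared_par, int rec_every,
                   bool heun, double w0, double rd0) {
  QGrid g(mu_grid, sg_grid);
  Shared sp;
  sp.K = shared_par["K"]; sp.J = shared_par["J"]; sp.a = shared_par["a"];
  sp.b = shared_par["b"]; sp.tau_w = shared_par["tau_w"];
  sp.E_w = shared_par["E_w"]; sp.Cap = shared_par["C"];
  sp.tau_d = shared_par["tau_d"]; sp.delay_kind = shared_par["delay_kind"];
  int nsig = mu_ext.size();
  double KJ = sp.K * sp.J, KJ2 = sp.K * sp.J * sp.J;
  // state: mu_f, sg_f, w, rd
  double st[4];
  {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, 0.0);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, 0.0);
    st[0] = mu_e + KJ * rd0;
    st[1] = std::sqrt(s2_e + KJ2 * rd0);
    st[2] = w0; st[3] = rd0;
  }
  double r_cur = 0.0, Vi_cur = 0.0;
  auto deriv = [&](const double *s, double t, double *ds, bool &sg_inst,
                   double &sg_target) {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, t);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, t);
    double rd = s[3];
    double mu_syn = mu_e + KJ * rd;
    double sg_syn = std::sqrt(s2_e + KJ2 * rd);
    double mu_eff = s[0] - s[2] / sp.Cap;
    double sg_eff = s[1];
    int i, j; double fx, fy;
    g.locate(mu_eff, sg_eff, i, j, fx, fy);
    double ri = g.val(r_inf.begin(), i, j, fx, fy);
    double Vi = g.val(V_inf.begin(), i, j, fx, fy);
    double tmu = g.val(tau_mu.begin(), i, j, fx, fy);
    double tsg = g.val(tau_sg.begin(), i, j, fx, fy);
    r_cur = ri; Vi_cur = Vi;
    ds[0] = (mu_syn - s[0]) / std::max(tmu, 1e-3);
    if (tsg < 2.0 * dt) { sg_inst = true; sg_target = sg_syn; ds[1] = 0.0; }
    else { sg_inst = false; sg_target = 0.0; ds[1] = (sg_syn - s[1]) / tsg; }
    ds[2] = (sp.a * (Vi - sp.E_w) - s[2]) / sp.tau_w + sp.b * ri;
    ds[3] = (sp.delay_kind == 1) ? (ri - rd) / sp.tau_d : 0.0;
  };
  int n_rec = n_steps / rec_every;
  NumericVector rate(n_rec), wv(n_rec), rdv(n_rec), Vv(n_rec);
  double acc = 0.0;
  int n_d = (sp.delay_kind == 2) ? std::max(1, (int)std::lround((double)shared_par["d"] / dt)) : 0;
  std::vector<double> rbuf;
  if (sp.delay_kind == 2) rbuf.assign(n_steps + 1, 0.0);
  double ds1[4], ds2[4], pred[4];
  bool inst1, inst2; double tgt1, tgt2;
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    deriv(st, t, ds1, inst1, tgt1);
    if (heun) {
      for (int q = 0; q < 4; ++q) pred[q] = st[q] + dt * ds1[q];
      if (inst1) pred[1] = tgt1;
      deriv(pred, t + dt, ds2, inst2, tgt2);
      for (int q = 0; q < 4; ++q) st[q] += 0.5 * dt * (ds1[q] + ds2[q]);
      if (inst2) st[1] = tgt2;
    } else {
      for (int q = 0; q < 4; ++q) st[q] += dt * ds1[q];
      if (inst1) st[1] = tgt1;
    }
    double r_out = std::max(r_cur, 0.0);
    if (sp.delay_kind == 2) {
      rbuf[step + 1] = r_out;
      st[3] = (step + 1 - n_d >= 0) ? rbuf[step + 1 - n_d] : 0.0;
    } else if (sp.delay_kind == 0) st[3] = r_out;
    acc += r_out;
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      rate[k] = acc / rec_every; acc = 0.0;
      wv[k] = st[2]; rdv[k] = st[3]; Vv[k] = Vi_cur;
    }
  }
  return List::create(_["rate"] = rate, _["mean_w"] = wv, _["r_d"] = rdv,
                      _["mean_V"] = Vv);
}

// ---------------------------------------------------------------------------
// LN_dos: damped-oscillator second-order filter for mu, first-order for sigma
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_lndos(NumericVector mu_grid, NumericVector sg_grid,
                   NumericMatrix r_inf, NumericMatrix V_inf,
                   NumericMatrix tau_q, NumericMatrix omega_q,
                   NumericMatrix tau_sg,
                   NumericMatrix dmu_r, NumericMatrix dsg_r,
                   NumericVector mu_ext, NumericVector sig2_ext,
                   NumericVector mu_dot, double sdt,
                   double dt, int n_steps, List shared_par, int rec_every,
                   bool heun, double w0, double rd0) {
  QGrid g(mu_grid, sg_grid);
  Shared sp;
  sp.K = shared_par["K"]; sp.J = shared_par["J"]; sp.a = shared_par["a"];
  sp.b = shared_par["b"]; sp.tau_w = shared_par["tau_w"];
  sp.E_w = shared_par["E_w"]; sp.Cap = shared_par["C"];
  sp.tau_d = shared_par["tau_d"]; sp.delay_kind = shared_par["delay_kind"];
  int nsig = mu_ext.size();
  double KJ = sp.K * sp.J, KJ2 = sp.K * sp.J * sp.J;
  // state: mu_f, dmu_f, sg_f, w, rd
  double st[5];
  {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, 0.0);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, 0.0);
    st[0] = mu_e + KJ * rd0;
    st[1] = 0.0;
    st[2] = std::sqrt(s2_e + KJ2 * rd0);
    st[3] = w0; st[4] = rd0;
  }
  double r_cur = 0.0, Vi_cur = 0.0;
  // history of r for identical-delay derivative of r_d (not needed: mu_dot_syn
  // for identical delays uses dr(t-d)/dt which we approximate from the rate
  // history buffer)
  int n_d = (sp.delay_kind == 2) ? std::max(1, (int)std::lround((double)shared_par["d"] / dt)) : 0;
  std::vector<double> rbuf;
  if (sp.delay_kind == 2) rbuf.assign(n_steps + 2, 0.0);
  auto deriv = [&](const double *s, double t, int step, double *ds,
                   bool &sg_inst, double &sg_target) {
    double mu_e = sig_at(mu_ext.begin(), nsig, sdt, t);
    double s2_e = sig_at(sig2_ext.begin(), nsig, sdt, t);
    double mud_e = sig_at(mu_dot.begin(), nsig, sdt, t);
    double rd = s[4];
    double mu_syn = mu_e + KJ * rd;
    double sg_syn = std::sqrt(s2_e + KJ2 * rd);
    double mu_tot = mu_syn - s[3] / sp.Cap;
    // filter parameters adapt to the *total* input moments
    int i, j; double fx, fy;
    g.locate(mu_tot, sg_syn, i, j, fx, fy);
    double tau = std::max(g.val(tau_q.begin(), i, j, fx, fy), 1e-3);
    double om = g.val(omega_q.begin(), i, j, fx, fy);
    double tsg = g.val(tau_sg.begin(), i, j, fx, fy);
    // output nonlinearity at the *effective* moments
    double mu_eff = s[0] - s[3] / sp.Cap;
    int i2, j2; double fx2, fy2;
    g.locate(mu_eff, s[2], i2, j2, fx2, fy2);
    double ri = g.val(r_inf.begin(), i2, j2, fx2, fy2);
    double Vi = g.val(V_inf.begin(), i2, j2, fx2, fy2);
    r_cur = ri; Vi_cur = Vi;
    // d mu_syn / dt, by delay kind
    double mu_syn_dot;
    if (sp.delay_kind == 1) mu_syn_dot = mud_e + KJ * (ri - rd) / sp.tau_d;
    else if (sp.delay_kind == 2) {
      double rdot = 0.0;
      int kk = step + 1 - n_d;
      if (kk >= 1) rdot = (rbuf[kk] - rbuf[kk - 1]) / dt;
      mu_syn_dot = mud_e + KJ * rdot;
    } else if (sp.K > 0) {
      double dmu_ri = g.val(dmu_r.begin(), i2, j2, fx2, fy2);
      double dsg_ri = g.val(dsg_r.begin(), i2, j2, fx2, fy2);
      double W = sp.a * (Vi - sp.E_w) - s[3];
      double dmueff = s[1] - (W / sp.tau_w + sp.b * ri) / sp.Cap;
      double dsgf = (tsg < 2.0 * dt) ? 0.0 : (sg_syn - s[2]) / tsg;
      mu_syn_dot = mud_e + KJ * (dmu_ri * dmueff + dsg_ri * dsgf);
    } else mu_syn_dot = mud_e;
    double B = (1.0 + tau * tau * om * om) / tau;
    ds[0] = s[1];
    ds[1] = B * (mu_syn / tau + mu_syn_dot) - 2.0 / tau * s[1] -
            (1.0 / (tau * tau) + om * om) * s[0];
    if (tsg < 2.0 * dt) { sg_inst = true; sg_target = sg_syn; ds[2] = 0.0; }
    else { sg_inst = false; sg_target = 0.0; ds[2] = (sg_syn - s[2]) / tsg; }
    ds[3] = (sp.a * (Vi - sp.E_w) - s[3]) / sp.tau_w + sp.b * ri;
    ds[4] = (sp.delay_kind == 1) ? (ri - rd) / sp.tau_d : 0.0;
  };
  int n_rec = n_steps / rec_every;
  NumericVector rate(n_rec), wv(n_rec), rdv(n_rec), Vv(n_rec);
  double acc = 0.0;
  double ds1[5], ds2[5], pred[5];
  bool inst1, inst2; double tgt1, tgt2;
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    deriv(st, t, step, ds1, inst1, tgt1);
    if (heun) {
      for (int q = 0; q < 5; ++q) pred[q] = st[q] + dt * ds1[q];
      if (inst1) pred[2] = tgt1;
      deriv(pred, t + dt, step, ds2, inst2, tgt2);
      for (int q = 0; q < 5; ++q) st[q] += 0.5 * dt * (ds1[q] + ds2[q]);
      if (inst2) st[2] = tgt2;
    } else {
      for (int q = 0; q < 5; ++q) st[q] += dt * ds1[q];
      if (inst1) st[2] = tgt1;
    }
    double r_out = std::max(r_cur, 0.0);
    if (sp.delay_kind == 2) {
      rbuf[step + 1] = r_out;
      st[4] = (step + 1 - n_d >= 0) ? rbuf[step + 1 - n_d] : 0.0;
    } else if (sp.delay_kind == 0) st[4] = r_out;
    acc += r_out;
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      rate[k] = acc / rec_every; acc = 0.0;
      wv[k] = st[3]; rdv[k] = st[4]; Vv[k] = Vi_cur;
    }
  }
  return List::create(_["rate"] = rate, _["mean_w"] = wv, _["r_d"] = rdv,
                      _["mean_V"] = Vv);
}
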