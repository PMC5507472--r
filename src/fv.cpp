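#include "fprate_common.h"
using namespace Rcpp;

// Assemble the Scharfetter-Gummel bands of the discrete drift-diffusion
// operator A (units 1/ms) on a grid with N cells: dp/dt = A p (+ reinjection).
// gface has N+1 entries, the membrane drift g(V) at the cell faces.
// The absorbing outflow at V_s is folded into diag[N-1]; the outflow
// coefficient w_out (rate = w_out * p[N-1], kHz) is returned separately.
static void fv_bands(int n, const double *gface, double mu, double D,
                     double dV, double *sub, double *diag, double *sup,
                     double &w_out) {
  std::vector<double> ap(n + 1), am(n + 1);
  ap[0] = am[0] = 0.0; // reflecting face at V_lb: zero flux
  for (int j = 1; j < n; ++j) sg_face(gface[j] + mu, D, dV, ap[j], am[j]);
  w_out = sg_outflow(gface[n] + mu, D, dV);
  for (int m = 0; m < n; ++m) {
    sub[m] = (m > 0) ? ap[m] / dV : 0.0;
    sup[m] = (m < n - 1) ? am[m + 1] / dV : 0.0;
    double out = (m < n - 1) ? ap[m + 1] : w_out;
    diag[m] = -(am[m] + out) / dV;
  }
}

// [[Rcpp::export]]
List cpp_fv_operator(NumericVector gface, double mu, double sigma2, double dV) {
  int n = gface.size() - 1;
  NumericVector sub(n), diag(n), sup(n);
  double w_out;
  fv_bands(n, gface.begin(), mu, 0.5 * sigma2, dV,
           sub.begin(), diag.begin(), sup.begin(), w_out);
  return List::create(_["sub"] = sub, _["diag"] = diag, _["sup"] = sup,
                      _["w_out"] = w_out);
}

// One implicit Euler step (I - dt A) p^{n+1} = p^n + g, g the reinjected
// probability (dt/dV * delayed rate) at the reset cell.
// [[Rcpp::export]]
NumericVector cpp_fv_step(NumericVector p, NumericVector sub,
                          NumericVector diag, NumericVector sup,
                          double dt, int m_r, double reinject_rate,
                          double dV) {
  int n = p.size();
  std::vector<double> a(n), b(n), c(n), rhs(n), cp(n);
  for (int i = 0; i < n; ++i) {
    a[i] = -dt * sub[i];
    b[i] = 1.0 - dt * diag[i];
    c[i] = -dt * sup[i];
    rhs[i] = p[i];
  }
  rhs[m_r] += dt / dV * reinject_rate;
  thomas_real(n, a.data(), b.data(), c.data(), rhs.data(), cp.data());
  return NumericVector(rhs.begin(), rhs.end());
}

// Direct stationary solve of the finite-volume system with reinjection:
// A p + (r/dV) e_{m_r} = 0, r = w_out p[N-1], normalized so that
// sum(p) dV + r T_ref = 1.  The one-dimensional nullspace is pinned by
// setting p[N-1] = 1 and solving rows 0..N-2 (row N-1 is redundant by
// probability conservation), then renormalizing.
// [[Rcpp::export]]
List cpp_stationary(NumericVector gface, double mu, double sigma2,
                    double dV, double Vlb, int m_r, double Tref) {
  int n = gface.size() - 1;
  std::vector<double> sub(n), diag(n), sup(n);
  double w_out;
  fv_bands(n, gface.begin(), mu, 0.5 * sigma2, dV,
           sub.data(), diag.data(), sup.data(), w_out);
  int nu = n - 1; // unknowns p_0 .. p_{n-2}
  std::vector<double> rhs(nu, 0.0), cp(nu);
  rhs[nu - 1] = -sup[nu - 1] * 1.0;   // coupling to known p[n-1] = 1
  rhs[m_r]   -= w_out / dV;           // reinjected outflow, p[n-1] = 1
  thomas_real(nu, sub.data(), diag.data(), sup.data(), rhs.data(), cp.data());
  std::vector<double> p(n);
  for (int i = 0; i < nu; ++i) p[i] = rhs[i];
  p[n - 1] = 1.0;
  double r_raw = w_out * p[n - 1];
  double mass = 0.0, vsum = 0.0;
  for (int i = 0; i < n; ++i) mass += p[i];
  mass *= dV;
  double Z = mass + r_raw * Tref;
  double meanV = 0.0;
  for (int i = 0; i < n; ++i) {
    double Vm = Vlb + (i + 0.5) * dV;
    p[i] /= Z;
    vsum += Vm * p[i];
    meanV += p[i];
  }
  double r = r_raw / Z;
  // in the deeply quiescent regime the outflow cell's density falls below
  // double precision relative to the bulk and the pinned nullspace can come
  // back sign-flipped: clamp sub-precision negatives
  double pmax = 0.0;
  for (int i = 0; i < n; ++i) pmax = std::max(pmax, p[i]);
  for (int i = 0; i < n; ++i)
    if (p[i] < 0 && p[i] > -1e-12 * pmax) p[i] = 0.0;
  if (r < 0 && r > -1e-12) r = 0.0;
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["r_inf"] = r,
                      _["mean_V_inf"] = vsum / meanV,
                      _["refractory_mass"] = r * Tref,
                      _["w_out"] = w_out);
}

// Time integration of the Fokker-Planck mean-field model: per step the
// operator is rebuilt at the current total moments (semi-implicit
// linearization), the tridiagonal system solved, the rate read off the
// ghost-cell flux, and mean adaptation / delayed rate advanced explicitly.
// delay_kind: 0 = none, 1 = exponential (ODE), 2 = identical (ring buffer).
// [[Rcpp::export]]
List cpp_run_fp(NumericVector gface, double dV, double Vlb, int m_r,
                NumericVector p0, double dt, int n_steps,
                NumericVector mu_ext, NumericVector sig2_ext,
                double K, double J, int delay_kind, double tau_d,
                double d_fixed, double a, double b, double tau_w,
                double E_w, double Cap, double Tref,
                double w0, double rd0, int rec_every,
                double sigma2_floor, bool keep_rate) {
  int n = gface.size() - 1;
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> sub(n), diag(n), sup(n), A(n), B(n), C(n), rhs(n), cp(n);
  int n_ref = std::max(1, (int)std::ceil(Tref / dt));
  std::vector<double> r_hist(n_steps + 2, 0.0); // r_hist[k] = rate at step k
  int n_d = (delay_kind == 2) ? std::max(1, (int)std::lround(d_fixed / dt)) : 0;
  double w = w0, rd = rd0;
  double meanV_prev = 0.0;
  {
    double s = 0.0, sv = 0.0;
    for (int i = 0; i < n; ++i) { s += p[i]; sv += (Vlb + (i + 0.5) * dV) * p[i]; }
    meanV_prev = sv / s;
  }
  int n_rec = n_steps / rec_every;
  NumericVector rate_bin(n_rec), meanV_rec(n_rec), w_rec(n_rec), rd_rec(n_rec);
  NumericVector r_full = keep_rate ? NumericVector(n_steps) : NumericVector(0);
  double acc = 0.0;
  double mass_err_max = 0.0;
  double w_out = 0.0;
  for (int step = 0; step < n_steps; ++step) {
    double mu_syn = mu_ext[step] + J * K * rd;
    double sig2 = sig2_ext[step] + J * J * K * rd;
    if (sig2 < sigma2_floor)
      stop("total input variance fell below the supported floor");
    double mu_tot = mu_syn - w / Cap;
    fv_bands(n, gface.begin(), mu_tot, 0.5 * sig2, dV,
             sub.data(), diag.data(), sup.data(), w_out);
    for (int i = 0; i < n; ++i) {
      A[i] = -dt * sub[i];
      B[i] = 1.0 - dt * diag[i];
      C[i] = -dt * sup[i];
      rhs[i] = p[i];
    }
    int k_re = step + 1 - n_ref;
    double r_rein = (k_re >= 0) ? r_hist[k_re] : 0.0;
    rhs[m_r] += dt / dV * r_rein;
    thomas_real(n, A.data(), B.data(), C.data(), rhs.data(), cp.data());
    for (int i = 0; i < n; ++i) p[i] = rhs[i];
    double r_new = w_out * p[n - 1];
    r_hist[step + 1] = r_new;
    // probability bookkeeping: density mass + refractory pipeline
    double mass = 0.0, sv = 0.0;
    for (int i = 0; i < n; ++i) { mass += p[i]; sv += (Vlb + (i + 0.5) * dV) * p[i]; }
    double pipeline = 0.0;
    for (int k = step + 2 - n_ref; k <= step + 1; ++k)
      if (k >= 0) pipeline += r_hist[k] * dt;
    double err = std::fabs(mass * dV + pipeline - 1.0);
    if (err > mass_err_max) mass_err_max = err;
    double meanV = (mass > 0) ? sv / mass : meanV_prev;
    meanV_prev = meanV;
    w += dt * ((a * (meanV - E_w) - w) / tau_w + b * r_new);
    if (delay_kind == 1)      rd += dt * (r_new - rd) / tau_d;
    else if (delay_kind == 2) rd = (step + 1 - n_d >= 0) ? r_hist[step + 1 - n_d] : 0.0;
    else                      rd = r_new;
    acc += r_new;
    if (keep_rate) r_full[step] = r_new;
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      rate_bin[k] = acc / rec_every;
      meanV_rec[k] = meanV;
      w_rec[k] = w;
      rd_rec[k] = rd;
      acc = 0.0;
    }
  }
  NumericVector pv(p.begin(), p.end());
  return List::create(_["rate"] = rate_bin, _["mean_V"] = meanV_rec,
                      _["mean_w"] = w_rec, _["r_d"] = rd_rec,
                      _["p_final"] = pv, _["mass_err_max"] = mass_err_max,
                      _["rate_full"] = r_full);
}

// Linearized Fokker-Planck system in the Fourier domain: for each frequency
// f solve (i 2 pi f I - A) phat = source, where A is the discrete operator
// (tridiagonal bands + rank-one reinjection handled by Sherman-Morrison) and
// the source is the directional derivative of the full operator applied to
// the stationary density.  Returns the complex rate responses per unit
// modulation of mu and of sigma^2.
// [[Rcpp::export]]
List cpp_linear_response(NumericVector gface, double mu, double sigma2,
                         double dV, double Vlb, int m_r, double Tref,
                         NumericVector freq, double h_mu, double h_s2) {
  int n = gface.size() - 1;
  List st = cpp_stationary(gface, mu, sigma2, dV, Vlb, m_r, Tref);
  NumericVector pinf = st["p"];
  double w_out = st["w_out"];

  // directional derivatives of the operator applied to p_inf (full operator:
  // tridiagonal bands + reinjection of the outflow into the reset cell)
  auto apply_full = [&](double m, double s2, std::vector<double> &out) {
    std::vector<double> sb(n), dg(n), sp(n);
    double wo;
    fv_bands(n, gface.begin(), m, 0.5 * s2, dV, sb.data(), dg.data(),
             sp.data(), wo);
    for (int i = 0; i < n; ++i) {
      double v = dg[i] * pinf[i];
      if (i > 0) v += sb[i] * pinf[i - 1];
      if (i < n - 1) v += sp[i] * pinf[i + 1];
      out[i] = v;
    }
    out[m_r] += wo * pinf[n - 1] / dV;
  };
  std::vector<double> fp(n), fm(n), smu(n), ssig(n);
  apply_full(mu + h_mu, sigma2, fp);
  apply_full(mu - h_mu, sigma2, fm);
  for (int i = 0; i < n; ++i) smu[i] = (fp[i] - fm[i]) / (2 * h_mu);
  apply_full(mu, sigma2 + h_s2, fp);
  apply_full(mu, sigma2 - h_s2, fm);
  for (int i = 0; i < n; ++i) ssig[i] = (fp[i] - fm[i]) / (2 * h_s2);
  // derivative of the outflow coefficient (enters the observed rate)
  std::vector<double> sb(n), dg(n), sp(n);
  double wo_p, wo_m;
  fv_bands(n, gface.begin(), mu + h_mu, 0.5 * sigma2, dV, sb.data(), dg.data(), sp.data(), wo_p);
  fv_bands(n, gface.begin(), mu - h_mu, 0.5 * sigma2, dV, sb.data(), dg.data(), sp.data(), wo_m);
  double dw_mu = (wo_p - wo_m) / (2 * h_mu);
  fv_bands(n, gface.begin(), mu, 0.5 * (sigma2 + h_s2), dV, sb.data(), dg.data(), sp.data(), wo_p);
  fv_bands(n, gface.begin(), mu, 0.5 * (sigma2 - h_s2), dV, sb.data(), dg.data(), sp.data(), wo_m);
  double dw_s2 = (wo_p - wo_m) / (2 * h_s2);

  fv_bands(n, gface.begin(), mu, 0.5 * sigma2, dV, sb.data(), dg.data(),
           sp.data(), wo_p); // base bands (wo_p == w_out)

  int nf = freq.size();
  ComplexVector Rmu(nf), Rs2(nf);
  std::vector<cplx> a(n), bb(n), c(n), y(n), z(n), cp(n);
  for (int k = 0; k < nf; ++k) {
    cplx iw(0.0, 2.0 * M_PI * freq[k]);
    cplx delay = std::exp(-iw * Tref);
    for (int i = 0; i < n; ++i) {
      a[i] = -cplx(sb[i]);
      bb[i] = iw - cplx(dg[i]);
      c[i] = -cplx(sp[i]);
    }
    // Sherman-Morrison for the reinjection column u = e_{m_r} w_out delay/dV,
    // v = e_{n-1}:  (M - u v^T) phat = s
    for (int i = 0; i < n; ++i) z[i] = 0.0;
    z[m_r] = w_out * delay / dV;
    thomas_cplx(n, a.data(), bb.data(), c.data(), z.data(), cp.data());
    // mu source
    for (int i = 0; i < n; ++i) y[i] = smu[i];
    y[m_r] += (delay - 1.0) * dw_mu * pinf[n - 1] / dV; // reinjection part carries the delay
    thomas_cplx(n, a.data(), bb.data(), c.data(), y.data(), cp.data());
    cplx plast = y[n - 1] / (1.0 - z[n - 1]);
    cplx rmu = w_out * plast + dw_mu * pinf[n - 1];
    Rmu[k] = Rcomplex{rmu.real(), rmu.imag()};
    // sigma^2 source
    for (int i = 0; i < n; ++i) y[i] = ssig[i];
    y[m_r] += (delay - 1.0) * dw_s2 * pinf[n - 1] / dV;
    thomas_cplx(n, a.data(), bb.data(), c.data(), y.data(), cp.data());
    plast = y[n - 1] / (1.0 - z[n - 1]);
    cplx rs2 = w_out * plast + dw_s2 * pinf[n - 1];
    Rs2[k] = Rcomplex{rs2.real(), rs2.imag()};
  }
  return List::create(_["R_mu"] = Rmu, _["R_sigma2"] = Rs2,
                      _["r_inf"] = st["r_inf"],
                      _["mean_V_inf"] = st["mean_V_inf"]);
}
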