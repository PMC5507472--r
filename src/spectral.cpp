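#include "fprate_common.h"
using namespace Rcpp;

// Backward exponential (one-term Magnus) integration of the first-order
// system for the eigenflux q and eigenfunction phi of the Fokker-Planck
// operator,
//   -d/dV (q, phi)^T = A(V) (q, phi)^T,
//   A = [[0, lambda], [2/sigma^2, -2 (g(V) + mu)/sigma^2]],
// from V_s (phi = 0, q = 1) down to V_lb, with the reinjection jump
// q(V_r-) = q(V_r+) - q(V_s) (times e^{-lambda T_ref} in refractory mode)
// applied at the reset node.  Stepping down by dV multiplies the state by
// exp(A(V_mid) dV).  The state is rescaled by its max modulus at fixed
// checkpoints (every `resc` steps); the accumulated log scale is returned so
// that callers can reconstruct magnitudes, while roots of q(V_lb) are
// unaffected (the scale is positive real and varies smoothly with lambda).
//
// nodes: V_k = Vlb + k dV, k = 0..n-1 (V_{n-1} = V_s); g_mid[k] = g at the
// midpoint of [V_k, V_{k+1}], k = 0..n-2; k_r = node index of V_r.

static const int RESC_EVERY = 128;

// [[Rcpp::export]]
List cpp_backward_flux(double lam_re, double lam_im, NumericVector g_mid,
                       double dV, double mu, double sigma2, int k_r,
                       double Tref, bool refr_mode, bool want_fun) {
  int n = g_mid.size() + 1;
  cplx lam(lam_re, lam_im);
  cplx q(1.0, 0.0), phi(0.0, 0.0);
  cplx qs_jump = refr_mode ? std::exp(-lam * Tref) : cplx(1.0, 0.0);
  double logs = 0.0;
  cplx twoOs2 = cplx(2.0 / sigma2, 0.0);
  cplx lam_b = lam; // A12
  std::vector<cplx> phi_arr, q_arr;
  if (want_fun) { phi_arr.assign(n, cplx(0, 0)); q_arr.assign(n, cplx(0, 0)); }
  if (want_fun) { phi_arr[n - 1] = phi; q_arr[n - 1] = q; }
  int steps = 0;
  for (int k = n - 2; k >= 0; --k) {
    double d = -2.0 * (g_mid[k] + mu) / sigma2 * dV;
    cplx e11, e12, e21, e22;
    expm2x2(lam_b * dV, twoOs2 * dV, cplx(d, 0.0), e11, e12, e21, e22);
    cplx qn = e11 * q + e12 * phi;
    cplx pn = e21 * q + e22 * phi;
    q = qn; phi = pn;
    if (k == k_r) q -= qs_jump;
    if (want_fun) { phi_arr[k] = phi; q_arr[k] = q; }
    if (++steps % RESC_EVERY == 0) {
      double m = std::max(std::abs(q), std::abs(phi));
      if (m > 0) {
        q /= m; phi /= m; qs_jump /= m; logs += std::log(m);
        if (want_fun) {
          for (int j = k; j < n; ++j) { phi_arr[j] /= m; q_arr[j] /= m; }
        }
      }
    }
  }
  List out = List::create(_["q_lb_re"] = q.real(), _["q_lb_im"] = q.imag(),
                          _["log_scale"] = logs);
  if (want_fun) {
    ComplexVector pv(n), qv(n);
    for (int j = 0; j < n; ++j) {
      pv[j] = Rcomplex{phi_arr[j].real(), phi_arr[j].imag()};
      qv[j] = Rcomplex{q_arr[j].real(), q_arr[j].imag()};
    }
    out["phi"] = pv;
    out["q"] = qv;
  }
  return out;
}

// Dense scan of the lower-bound flux over real eigenvalue candidates
// (all-real spectrum regime at strongly hyperpolarizing mean input).
// Returns q(V_lb) at the common checkpoint-rescaled scale (column 1) and the
// accumulated log scale (column 2); sign changes of column 1 bracket
// eigenvalues because the scale factors are positive.
// [[Rcpp::export]]
NumericMatrix cpp_scan_real(NumericVector lams, NumericVector g_mid,
                            double dV, double mu, double sigma2, int k_r,
                            double Tref, bool refr_mode) {
  int n = g_mid.size() + 1;
  int nl = lams.size();
  NumericMatrix out(nl, 2);
  double c = 2.0 / sigma2 * dV;
  for (int il = 0; il < nl; ++il) {
    double lam = lams[il];
    double q = 1.0, phi = 0.0;
    double qs_jump = refr_mode ? std::exp(-lam * Tref) : 1.0;
    double logs = 0.0;
    double b = lam * dV;
    int steps = 0;
    for (int k = n - 2; k >= 0; --k) {
      double d = -2.0 * (g_mid[k] + mu) / sigma2 * dV;
      double e11, e12, e21, e22;
      expm2x2_real(b, c, d, e11, e12, e21, e22);
      double qn = e11 * q + e12 * phi;
      double pn = e21 * q + e22 * phi;
      q = qn; phi = pn;
      if (k == k_r) q -= qs_jump;
      if (++steps % RESC_EVERY == 0) {
        double m = std::max(std::fabs(q), std::fabs(phi));
        if (m > 0) { q /= m; phi /= m; qs_jump /= m; logs += std::log(m); }
      }
    }
    out(il, 0) = q;
    out(il, 1) = logs;
  }
  return out;
}

// Forward exponential integration of the adjoint eigenproblem
//   L* psi = (g(V) + mu) psi' + sigma^2/2 psi'' = lambda psi
// as the first-order system d/dV (psi, u)^T = B(V) (psi, u)^T with
// B = [[0, 1], [2 lambda / sigma^2, -2 (g + mu)/sigma^2]], from V_lb with
// psi(V_lb) = 1, psi'(V_lb) = 0 (reflecting condition) up to V_s.  The
// derivative is continuous at V_r by construction; the remaining boundary
// condition psi(V_s) = psi(V_r) (times e^{-lambda T_ref}) is returned as a
// residual for the caller to check.
// [[Rcpp::export]]
List cpp_solve_adjoint(double lam_re, double lam_im, NumericVector g_mid,
                       double dV, double mu, double sigma2, int k_r,
                       double Tref, bool refr_mode) {
  int n = g_mid.size() + 1;
  cplx lam(lam_re, lam_im);
  cplx psi(1.0, 0.0), u(0.0, 0.0);
  std::vector<cplx> psi_arr(n);
  psi_arr[0] = psi;
  double logs = 0.0;
  cplx c0 = 2.0 * lam / sigma2 * dV;
  for (int k = 0; k < n - 1; ++k) {
    double d = -2.0 * (g_mid[k] + mu) / sigma2 * dV;
    cplx e11, e12, e21, e22;
    expm2x2(cplx(dV, 0.0), c0, cplx(d, 0.0), e11, e12, e21, e22);
    cplx pn = e11 * psi + e12 * u;
    cplx un = e21 * psi + e22 * u;
    psi = pn; u = un;
    psi_arr[k + 1] = psi;
    double m = std::max(std::abs(psi), std::abs(u));
    if (m > 1e100) {
      psi /= m; u /= m; logs += std::log(m);
      for (int j = 0; j <= k + 1; ++j) psi_arr[j] /= m;
    }
  }
  cplx fac = refr_mode ? std::exp(-lam * Tref) : cplx(1.0, 0.0);
  cplx resid = psi_arr[n - 1] - psi_arr[k_r] * fac;
  double mx = 0.0;
  for (int j = 0; j < n; ++j) mx = std::max(mx, std::abs(psi_arr[j]));
  ComplexVector pv(n);
  for (int j = 0; j < n; ++j)
    pv[j] = Rcomplex{psi_arr[j].real(), psi_arr[j].imag()};
  return List::create(_["psi"] = pv, _["log_scale"] = logs,
                      _["resid_re"] = resid.real(),
                      _["resid_im"] = resid.imag(),
                      _["resid_rel"] = std::abs(resid) / mx);
}
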