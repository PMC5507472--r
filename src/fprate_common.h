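#ifndef FPRATE_COMMON_H
#define FPRATE_COMMON_H

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

typedef std::complex<double> cplx;

// Membrane drift of the EIF voltage equation, g(V) = [I_L(V) + I_exp(V)]/C,
// in mV/ms.  The total drift at input mean mu is g(V) + mu.
inline double eif_drift(double V, double C, double gL, double EL,
                        double DT, double VT) {
  return (-gL * (V - EL) + gL * DT * std::exp((V - VT) / DT)) / C;
}

// Scharfetter-Gummel face coefficients.  The flux through a face with drift v,
// diffusion D and spacing dV is q = aplus * p_left - aminus * p_right with
//   aplus  = v / (1 - exp(-v dV / D)),   aminus = v / (exp(v dV / D) - 1).
// Both reduce to D/dV +- v/2 in the vanishing-drift limit (centered
// differences) and to the upwind flux for |v| dV >> D.
inline void sg_face(double v, double D, double dV,
                    double &aplus, double &aminus) {
  double x = v * dV / D;
  if (std::fabs(x) < 1e-10) {
    aplus  = D / dV + 0.5 * v;
    aminus = D / dV - 0.5 * v;
  } else {
    aplus  =  v / (-std::expm1(-x));
    aminus =  v /   std::expm1(x);
  }
}

// Outflow coefficient at the absorbing boundary V_s (ghost-cell closure):
// r = w_out * p_last with w_out = v (1 + e^{-x}) / (1 - e^{-x}).
inline double sg_outflow(double v, double D, double dV) {
  double x = v * dV / D;
  if (std::fabs(x) < 1e-10) return 2.0 * D / dV + 0.5 * v * x / 3.0;
  return v * (1.0 + std::exp(-x)) / (-std::expm1(-x));
}

// Thomas algorithm for a tridiagonal system, real coefficients.
// diag, sub, sup are the matrix bands (sub[i] multiplies x[i-1] in row i,
// sup[i] multiplies x[i+1]); rhs is overwritten with the solution.
inline void thomas_real(int n, const double *sub, const double *diag,
                        const double *sup, double *rhs, double *cp) {
  cp[0] = sup[0] / diag[0];
  rhs[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - sub[i] * cp[i - 1];
    cp[i] = sup[i] / m;
    rhs[i] = (rhs[i] - sub[i] * rhs[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
}

inline void thomas_cplx(int n, const cplx *sub, const cplx *diag,
                        const cplx *sup, cplx *rhs, cplx *cp) {
  cp[0] = sup[0] / diag[0];
  rhs[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    cplx m = diag[i] - sub[i] * cp[i - 1];
    cp[i] = sup[i] / m;
    rhs[i] = (rhs[i] - sub[i] * rhs[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
}

// Analytic matrix exponential of the 2x2 matrix M = [[0, b], [c, d]],
// exp(M) = e^{d/2} [cosh(D) I + sinh(D)/D (M - d/2 I)],  D = sqrt(d^2/4 + bc).
// Series branch for the sinhc when |D| is tiny.
inline void expm2x2(cplx b, cplx c, cplx d,
                    cplx &e11, cplx &e12, cplx &e21, cplx &e22) {
  cplx half = 0.5 * d;
  cplx disc = half * half + b * c;
  cplx D = std::sqrt(disc);
  cplx ch, shc; // cosh(D), sinh(D)/D
  if (std::abs(D) < 1e-6) {
    cplx D2 = disc;
    ch  = 1.0 + D2 / 2.0;
    shc = 1.0 + D2 / 6.0;
  } else {
    ch  = std::cosh(D);
    shc = std::sinh(D) / D;
  }
  cplx pref = std::exp(half);
  e11 = pref * (ch - shc * half);
  e12 = pref * (shc * b);
  e21 = pref * (shc * c);
  e22 = pref * (ch + shc * half);
}

// Real specialization (b, c, d real): disc may be negative, in which case
// cosh(i y) = cos(y), sinh(i y)/(i y) = sin(y)/y.
inline void expm2x2_real(double b, double c, double d,
                         double &e11, double &e12, double &e21, double &e22) {
  double half = 0.5 * d;
  double disc = half * half + b * c;
  double ch, shc;
  if (std::fabs(disc) < 1e-12) {
    ch = 1.0 + disc / 2.0;
    shc = 1.0 + disc / 6.0;
  } else if (disc > 0) {
    double D = std::sqrt(disc);
    ch = std::cosh(D);
    shc = std::sinh(D) / D;
  } else {
    double D = std::sqrt(-disc);
    ch = std::cos(D);
    shc = std::sin(D) / D;
  }
  double pref = std::exp(half);
  e11 = pref * (ch - shc * half);
  e12 = pref * (shc * b);
  e21 = pref * (shc * c);
  e22 = pref * (ch + shc * half);
}

#endif
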