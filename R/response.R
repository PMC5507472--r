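# Fourier-domain linear rate response functions of the EIF population and
# the semi-analytic filter approximations used by the LN cascade models.

#' Linear rate response spectrum
#'
#' Solves, for each modulation frequency, the Fokker-Planck system linearized
#' around the stationary solution at baseline moments (mu0, sigma0): the
#' complex rate response per unit modulation of the input mean,
#' \eqn{\hat R_\mu(f)}, and of the input standard deviation,
#' \eqn{\hat R_\sigma(f) = 2\sigma_0 \hat R_{\sigma^2}(f)}.  The linearized
#' boundary-value problems are solved at the discrete (finite-volume) level,
#' so the zero-frequency limits match finite differences of the discrete
#' stationary solve.
#'
#' @param mu0,sigma0 baseline input moments
#' @param f_grid strictly increasing modulation frequencies (kHz); default 64
#'   log-spaced points in [1e-3, 1]
#' @param grid a \code{\link{build_voltage_grid}} object
#' @param neuron a \code{\link{neuron_params}} object
#' @return an object of class \code{"response_spectrum"} with fields
#'   \code{f}, complex \code{R_mu}, \code{R_sigma}, \code{R_sigma2},
#'   \code{r_inf}, and the baseline moments
#' @export
linear_rate_response <- function(mu0, sigma0, f_grid = NULL, grid, neuron) {
  check_sigma_floor(sigma0)
  if (is.null(f_grid)) f_grid <- 10^seq(-3, 0, length.out = 64)
  if (any(diff(f_grid) <= 0)) stop("f_grid must be strictly increasing")
  res <- cpp_linear_response(grid$gface, mu0, sigma0^2, grid$dV, grid$V_lb,
                             grid$m_r - 1L, neuron$T_ref, f_grid,
                             1e-4, 1e-3 * sigma0^2)
  structure(list(f = f_grid, R_mu = res$R_mu,
                 R_sigma2 = res$R_sigma2,
                 R_sigma = 2 * sigma0 * res$R_sigma2,
                 r_inf = res$r_inf, mean_V_inf = res$mean_V_inf,
                 mu0 = mu0, sigma0 = sigma0, Delta_T = neuron$Delta_T),
            class = "response_spectrum")
}

# complex transfer function of the normalized exponential filter
lorentzian_tf <- function(f, tau) 1 / (1 + 2i * pi * f * tau)

# complex transfer function of the normalized damped-oscillator filter
# D(t) = B e^{-t/tau} cos(omega t), B = (1 + tau^2 omega^2)/tau
dos_tf <- function(f, tau, omega) {
  s <- 1 / tau + 2i * pi * f
  B <- (1 + tau^2 * omega^2) / tau
  B * s / (s^2 + omega^2)
}

# least-squares Lorentzian time constant for a normalized target spectrum
fit_lorentzian <- function(f, D_target, tau_range = c(0.01, 200)) {
  sse <- function(lt) {
    tau <- exp(lt)
    sum(Mod(lorentzian_tf(f, tau) - D_target)^2)
  }
  o <- stats::optimize(sse, log(tau_range), tol = 1e-10)
  exp(o$minimum)
}

#' Exponential filter fit for the mean-input response
#'
#' Normalizes the rate response by \eqn{\partial_\mu r_\infty} (so the filter
#' integrates to one, fixing \eqn{A_\mu = 1/\tau_\mu}) and extracts the decay
#' time.  \code{mode = "asymptotic"} matches the high-frequency limit
#' \eqn{\hat R_\mu \to r_\infty/(i2\pi f \Delta_T)}, giving
#' \eqn{\tau_\mu = \Delta_T\, \partial_\mu r_\infty / r_\infty};
#' \code{mode = "least_squares"} minimizes the complex residual of the
#' Lorentzian over the frequency window (the fit used by the LN_exp model).
#'
#' @param spec a \code{\link{linear_rate_response}} result
#' @param dmu_rinf \eqn{\partial_\mu r_\infty} at the baseline (1/mV)
#' @param mode fit mode
#' @return time constant \eqn{\tau_\mu} (ms)
#' @export
fit_exp_filter <- function(spec, dmu_rinf,
                           mode = c("least_squares", "asymptotic")) {
  mode <- match.arg(mode)
  if (!(dmu_rinf > 0)) stop("filter undefined for nonpositive d r_inf / d mu")
  if (mode == "asymptotic")
    return(spec$Delta_T * dmu_rinf / spec$r_inf)
  D <- spec$R_mu / dmu_rinf
  fit_lorentzian(spec$f, D)
}

# quadratic refinement of a grid argmax (in log f for log-spaced grids)
refine_argmax <- function(f, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(list(f = f[i], edge = i == 1 || i == length(y)))
  lx <- log(f[(i - 1):(i + 1)])
  yy <- y[(i - 1):(i + 1)]
  denom <- (yy[1] - 2 * yy[2] + yy[3])
  if (abs(denom) < 1e-300) return(list(f = f[i], edge = FALSE))
  dx <- 0.5 * (yy[1] - yy[3]) / denom
  dx <- max(-1, min(1, dx))
  list(f = exp(lx[2] + dx * (lx[3] - lx[2])), edge = FALSE)
}

#' Damped-oscillator filter fit for the mean-input response
#'
#' Fits \eqn{D_\mu(t) = B_\mu e^{-t/\tau}\cos(\omega t)} with DC
#' normalization \eqn{B_\mu = (1 + \tau^2\omega^2)/\tau}.  The two remaining
#' parameters are chosen to match the normalized response at the frequencies
#' where its real and imaginary parts peak in magnitude (quadratically
#' refined around the grid argmax), by minimizing the equally weighted
#' two-point complex mismatch.  A degenerate argmax at the grid edge falls
#' back to the exponential fit (\eqn{\omega = 0}).
#'
#' @inheritParams fit_exp_filter
#' @return list with \code{tau} (ms), \code{omega} (rad/ms) and the implied
#'   scale \code{B_mu}
#' @export
fit_dos_filter <- function(spec, dmu_rinf) {
  if (!(dmu_rinf > 0)) stop("filter undefined for nonpositive d r_inf / d mu")
  D <- spec$R_mu / dmu_rinf
  fR <- refine_argmax(spec$f, abs(Re(D)))
  fI <- refine_argmax(spec$f, abs(Im(D)))
  tau_exp <- fit_lorentzian(spec$f, D)
  if (fI$edge) {
    return(list(tau = tau_exp, omega = 0, B_mu = 1 / tau_exp, fallback = TRUE))
  }
  interp_c <- function(ft) {
    re <- stats::approx(log(spec$f), Re(D), xout = log(ft), rule = 2)$y
    im <- stats::approx(log(spec$f), Im(D), xout = log(ft), rule = 2)$y
    complex(real = re, imaginary = im)
  }
  targets <- c(interp_c(fR$f), interp_c(fI$f))
  obj <- function(par) {
    tau <- exp(par[1]); omega <- abs(par[2])
    model <- c(dos_tf(fR$f, tau, omega), dos_tf(fI$f, tau, omega))
    sum(Mod(model - targets)^2)
  }
  starts <- list(c(log(tau_exp), 2 * pi * fI$f), c(log(tau_exp), 0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  tau <- exp(best$par[1]); omega <- abs(best$par[2])
  list(tau = tau, omega = omega, B_mu = (1 + tau^2 * omega^2) / tau,
       fallback = FALSE, f_R = fR$f, f_I = fI$f)
}

#' Exponential filter fit for the noise-intensity response
#'
#' Least-squares Lorentzian fit of the normalized sigma response when
#' \eqn{\partial_\sigma r_\infty > 0}.  When that derivative is nonpositive
#' (large mean, small variance) the true filter relaxes essentially
#' instantaneously and cannot be represented by an exponential with
#' nonnegative time constant; the delta-filter limit \eqn{\tau_\sigma = 0}
#' is returned.
#'
#' @param spec a \code{\link{linear_rate_response}} result
#' @param dsigma_rinf \eqn{\partial_\sigma r_\infty} at the baseline
#' @return time constant \eqn{\tau_\sigma} (ms), possibly zero
#' @export
fit_sigma_filter <- function(spec, dsigma_rinf) {
  if (!(dsigma_rinf > 0)) return(0)
  D <- spec$R_sigma / dsigma_rinf
  fit_lorentzian(spec$f, D)
}
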