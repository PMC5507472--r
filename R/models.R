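# Time integration of the four reduced spike rate models, sharing the mean
# adaptation and delayed-rate dynamics and the precomputed quantity table.

#' One explicit update of the population-averaged adaptation current
#'
#' \eqn{d\langle w\rangle/dt = [a(\langle V\rangle_\infty - E_w) -
#' \langle w\rangle]/\tau_w + b\,r}.
#'
#' @param w current mean adaptation (pA)
#' @param mean_V_inf steady-state mean voltage at the model's evaluation
#'   point (mV)
#' @param r current spike rate (kHz)
#' @param neuron a \code{\link{neuron_params}} object
#' @param dt step (ms)
#' @param method \code{"euler"} or \code{"heun"}
#' @return updated \eqn{\langle w\rangle} (pA)
#' @export
step_mean_adaptation <- function(w, mean_V_inf, r, neuron, dt,
                                 method = c("euler", "heun")) {
  method <- match.arg(method)
  f <- function(w) (neuron$a * (mean_V_inf - neuron$E_w) - w) / neuron$tau_w +
    neuron$b * r
  k1 <- f(w)
  if (method == "euler") return(w + dt * k1)
  w + dt / 2 * (k1 + f(w + dt * k1))
}

#' One update of the delayed population rate
#'
#' Exponential delays are equivalent to the first-order relaxation
#' \eqn{dr_d/dt = (r - r_d)/\tau_d}; identical delays read a ring buffer of
#' past rates; without delays \eqn{r_d = r}.
#'
#' @param r_d current delayed rate (kHz)
#' @param r current rate (kHz)
#' @param coupling a \code{\link{coupling_params}} object
#' @param dt step (ms)
#' @param r_buffer past rates (most recent last), required for identical
#'   delays
#' @return updated \eqn{r_d} (kHz)
#' @export
step_delayed_rate <- function(r_d, r, coupling, dt, r_buffer = NULL) {
  switch(coupling$delay_kind,
         exponential = r_d + dt * (r - r_d) / coupling$tau_d,
         identical = {
           nd <- max(1L, round(coupling$d / dt))
           if (is.null(r_buffer) || length(r_buffer) < nd) 0
           else r_buffer[length(r_buffer) - nd + 1L]
         },
         none = r)
}

# interpolate a signal onto a uniform step grid and return the values plus
# smoothed first/second time derivatives (central differences at the signal's
# own resolution)
signal_with_derivs <- function(x, tt) {
  ts <- signal_times(x)
  v <- x$values
  n <- length(v)
  d1 <- c(v[2] - v[1], (v[-(1:2)] - v[1:(n - 2)]) / 2,
          v[n] - v[n - 1]) / x$dt
  d2 <- c(0, diff(v, differences = 2), 0) / x$dt^2
  list(v = stats::approx(ts, v, xout = tt, rule = 2)$y,
       d1 = stats::approx(ts, d1, xout = tt, rule = 2)$y,
       d2 = stats::approx(ts, d2, xout = tt, rule = 2)$y)
}

need_arrays <- function(table, names, model) {
  miss <- setdiff(names, names(table$arrays))
  if (length(miss))
    stop(sprintf("quantity table lacks arrays required by %s: %s",
                 model, paste(miss, collapse = ", ")))
}

shared_par_list <- function(neuron, coupling) {
  list(K = as.numeric(coupling$K), J = coupling$J, a = neuron$a,
       b = neuron$b, tau_w = neuron$tau_w, E_w = neuron$E_w, C = neuron$C,
       tau_d = coupling$tau_d, d = coupling$d,
       delay_kind = switch(coupling$delay_kind, none = 0L,
                           exponential = 1L, identical = 2L))
}

#' Integrate a reduced spike rate model
#'
#' Runs one of the four low-dimensional models derived from the
#' Fokker-Planck description on a time-varying external input, with shared
#' mean-adaptation and delayed-rate dynamics:
#' \describe{
#'   \item{\code{spec1}}{complex first-order equation driven by the dominant
#'     eigenvalue, \eqn{d\tilde r/dt = \lambda_1(\tilde r - r_\infty)},
#'     output \eqn{r = \max(\mathrm{Re}\,\tilde r, 0)}.}
#'   \item{\code{spec2}}{real second-order equation with lumped two-eigenvalue
#'     coefficients; requires \eqn{T_{ref} = 0} and (when coupled)
#'     exponential delays; negative excursions reset rate and slope to zero.}
#'   \item{\code{lnexp}}{exponential filters for mean and noise intensity
#'     with time constants looked up at the effective moments, followed by
#'     the stationary-rate nonlinearity.}
#'   \item{\code{lndos}}{damped-oscillator filter for the mean (parameters
#'     looked up at the total moments), exponential noise filter, same
#'     nonlinearity.}
#' }
#'
#' @param model one of \code{"spec1"}, \code{"spec2"}, \code{"lnexp"},
#'   \code{"lndos"}
#' @param table a \code{\link{precompute_quantities}} result (with the
#'   arrays the model needs)
#' @param neuron,coupling model parameters; the table must have been built
#'   for the same neuron parameters
#' @param mu_ext,sigma_ext_sq external input moments (\code{fp_signal}s);
#'   for \code{spec2}/\code{lndos} these should be smooth (Gaussian filtered,
#'   width at least 1 ms)
#' @param dt integration step (ms); default 0.01
#' @param T duration (ms)
#' @param method stepper, Heun (default) or Euler
#' @param w0,rd0 initial mean adaptation and delayed rate
#' @param rec_dt recording bin (ms); rates are bin averages
#' @return a \code{"population_trace"}
#' @export
run_rate_model <- function(model = c("spec1", "spec2", "lnexp", "lndos"),
                           table, neuron, coupling, mu_ext, sigma_ext_sq,
                           dt = 0.01, T = NULL, method = c("heun", "euler"),
                           w0 = 0, rd0 = 0, rec_dt = 1) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(inherits(table, "quantity_table"),
            inherits(neuron, "neuron_params"),
            inherits(coupling, "coupling_params"))
  if (model == "spec2") {
    if (neuron$T_ref > 0)
      stop("a nonzero refractory period is not supported by the spec2 model")
    if (coupling$K > 0 && coupling$J != 0 &&
        coupling$delay_kind != "exponential")
      stop("spec2 coefficients are implemented for exponential delays only")
  }
  if (!identical(params_hash(neuron), table$hash))
    stop("quantity table was precomputed for different neuron parameters")
  if (is.null(T)) T <- (length(mu_ext$values) - 1) * mu_ext$dt
  rec_every <- max(1L, round(rec_dt / dt))
  n_steps <- (floor(T / dt) %/% rec_every) * rec_every
  sdt <- mu_ext$dt
  n_sig <- floor(T / sdt) + 1L
  tt <- (seq_len(n_sig) - 1) * sdt
  mu_s <- signal_with_derivs(mu_ext, tt)
  s2_s <- signal_with_derivs(sigma_ext_sq, tt)
  heun <- method == "heun"
  sp <- shared_par_list(neuron, coupling)
  A <- table$arrays
  res <- switch(model,
    spec1 = {
      need_arrays(table, c("r_inf", "mean_V_inf", "lam1_re", "lam1_im"),
                  "spec1")
      cpp_run_spec1(table$mu, table$sigma, A$r_inf, A$mean_V_inf,
                    A$lam1_re, A$lam1_im, mu_s$v, s2_s$v, sdt, dt, n_steps,
                    sp, rec_every, heun, w0, rd0)
    },
    spec2 = {
      need_arrays(table, c("r_inf", "mean_V_inf", "lam1_re", "lam1_im",
                           "lam2_re", "lam2_im", "M", "S", "F_mu",
                           "F_sigma2", "d_mu_V_inf", "d_sigma2_V_inf"),
                  "spec2")
      cpp_run_spec2(table$mu, table$sigma, A$r_inf, A$mean_V_inf,
                    A$lam1_re, A$lam1_im, A$lam2_re, A$lam2_im,
                    A$M, A$S, A$F_mu, A$F_sigma2,
                    A$d_mu_V_inf, A$d_sigma2_V_inf,
                    mu_s$v, s2_s$v, mu_s$d1, mu_s$d2, s2_s$d1, s2_s$d2,
                    sdt, dt, n_steps, sp, rec_every, heun, w0, rd0)
    },
    lnexp = {
      need_arrays(table, c("r_inf", "mean_V_inf", "tau_mu", "tau_sigma"),
                  "lnexp")
      cpp_run_lnexp(table$mu, table$sigma, A$r_inf, A$mean_V_inf,
                    A$tau_mu, A$tau_sigma, mu_s$v, s2_s$v, sdt, dt, n_steps,
                    sp, rec_every, heun, w0, rd0)
    },
    lndos = {
      need_arrays(table, c("r_inf", "mean_V_inf", "tau", "omega",
                           "tau_sigma", "d_mu_r_inf", "d_sigma_r_inf"),
                  "lndos")
      cpp_run_lndos(table$mu, table$sigma, A$r_inf, A$mean_V_inf,
                    A$tau, A$omega, A$tau_sigma,
                    A$d_mu_r_inf, A$d_sigma_r_inf,
                    mu_s$v, s2_s$v, mu_s$d1, sdt, dt, n_steps,
                    sp, rec_every, heun, w0, rd0)
    })
  rec <- rec_every * dt
  structure(list(rate = signal(res$rate, rec, rec / 2, "kHz"),
                 mean_V = signal(res$mean_V, rec, rec, "mV"),
                 mean_w = signal(res$mean_w, rec, rec, "pA"),
                 r_d = signal(res$r_d, rec, rec, "kHz"),
                 n_clamped = res$n_clamped,
                 model = model), class = "population_trace")
}
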