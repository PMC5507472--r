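#' Neuron model parameters
#'
#' Container for the parameters of the adaptive exponential
#' integrate-and-fire (aEIF) neuron.  The membrane voltage obeys
#' \deqn{C \, dV/dt = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'   - w + I_{syn}(t),}
#' with a spike emitted when \eqn{V \ge V_s}, followed by reset to
#' \eqn{V_r}, adaptation increment \eqn{w \leftarrow w + b} and a clamp of
#' duration \code{T_ref}.  The adaptation current relaxes as
#' \eqn{\tau_w \, dw/dt = a (V - E_w) - w}.  Units are fixed package wide:
#' time ms, voltage mV, capacitance pF, conductance nS, current pA; the input
#' mean \eqn{\mu} carries mV/ms and the input variance \eqn{\sigma^2}
#' mV\eqn{^2}/ms (so \eqn{\sigma} carries mV\,ms\eqn{^{-1/2}}).
#'
#' Defaults describe a regular-spiking cortical pyramidal cell.
#' \code{V_lb} is the finite reflecting lower bound used by the
#' Fokker-Planck description (it plays no role in the particle simulation).
#'
#' @param C membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak reversal potential (mV)
#' @param Delta_T threshold slope factor (mV)
#' @param V_T effective threshold voltage (mV)
#' @param V_s spike voltage (mV)
#' @param V_r reset voltage (mV)
#' @param T_ref refractory period (ms)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param E_w adaptation reversal potential (mV)
#' @param tau_w adaptation time constant (ms)
#' @param V_lb lower bound voltage of the Fokker-Planck domain (mV)
#' @return an object of class \code{"neuron_params"}
#' @export
neuron_params <- function(C = 200, g_L = 10, E_L = -65, Delta_T = 1.5,
                          V_T = -50, V_s = -40, V_r = -70, T_ref = 0,
                          a = 4, b = 40, E_w = -80, tau_w = 200,
                          V_lb = -200) {
  stopifnot(C > 0, g_L > 0, Delta_T > 0, tau_w > 0, T_ref >= 0,
            a >= 0, b >= 0)
  if (!(V_lb < V_r && V_r < V_T && V_T < V_s))
    stop("voltage ordering must satisfy V_lb < V_r < V_T < V_s")
  structure(list(C = C, g_L = g_L, E_L = E_L, Delta_T = Delta_T,
                 V_T = V_T, V_s = V_s, V_r = V_r, T_ref = T_ref,
                 a = a, b = b, E_w = E_w, tau_w = tau_w, V_lb = V_lb),
            class = "neuron_params")
}

#' Recurrent coupling parameters
#'
#' Sparse random pulse coupling: each neuron receives input from \code{K}
#' presynaptic partners, each presynaptic spike causing a postsynaptic
#' voltage jump \code{J} (mV) after a propagation delay.  Delays are either
#' drawn once per connection from an exponential distribution with mean
#' \code{tau_d} (ms), identical (\code{d} ms), or absent.
#'
#' @param K in-degree (count, \code{K = 0} for an uncoupled population)
#' @param J synaptic strength (mV), positive for excitation
#' @param delay_kind one of \code{"exponential"}, \code{"identical"},
#'   \code{"none"}
#' @param tau_d mean delay (ms) for exponential delays
#' @param d fixed delay (ms) for identical delays
#' @return an object of class \code{"coupling_params"}
#' @export
coupling_params <- function(K = 0, J = 0, delay_kind = c("exponential",
                            "identical", "none"), tau_d = 3, d = 1) {
  delay_kind <- match.arg(delay_kind)
  stopifnot(K >= 0, K == round(K))
  if (delay_kind == "exponential" && !(tau_d > 0))
    stop("tau_d must be positive for exponential delays")
  if (delay_kind == "identical" && !(d >= 0))
    stop("d must be nonnegative for identical delays")
  structure(list(K = as.integer(K), J = J, delay_kind = delay_kind,
                 tau_d = tau_d, d = d),
            class = "coupling_params")
}

#' Ornstein-Uhlenbeck input process parameters
#'
#' Parameters of the stationary OU process used to generate time-varying
#' external input moments, plus the width of the Gaussian kernel applied to
#' the realization to make it sufficiently differentiable.  The stationary
#' law is Normal(\code{mean}, \code{theta}^2).
#'
#' @param mean stationary mean (mV/ms for a mean-input process,
#'   mV^2/ms for a variance process)
#' @param theta stationary standard deviation (same units as \code{mean})
#' @param tau_ou correlation time (ms)
#' @param sigma_t Gaussian smoothing width (ms); 0 disables smoothing
#' @return an object of class \code{"ou_params"}
#' @export
ou_params <- function(mean = 0, theta = 0, tau_ou = 50, sigma_t = 1) {
  stopifnot(tau_ou > 0, theta >= 0, sigma_t >= 0)
  structure(list(mean = mean, theta = theta, tau_ou = tau_ou,
                 sigma_t = sigma_t), class = "ou_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("aEIF neuron parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.coupling_params <- function(x, ...) {
  cat(sprintf("coupling: K = %d, J = %g mV, delays = %s\n", x$K, x$J,
              switch(x$delay_kind,
                     exponential = sprintf("Exp(mean %g ms)", x$tau_d),
                     identical = sprintf("identical %g ms", x$d),
                     none = "none")))
  invisible(x)
}

# deterministic short hash of the neuron parameters (polynomial rolling hash
# over the formatted values); keys precomputed quantity tables to the neuron
# model
params_hash <- function(neuron) {
  # only the detached EIF parameters enter the precomputed quantities;
  # adaptation (a, b, E_w, tau_w), coupling and input parameters do not
  eif <- neuron[c("C", "g_L", "E_L", "Delta_T", "V_T", "V_s", "V_r",
                  "T_ref", "V_lb")]
  s <- paste(names(eif), vapply(eif, function(v) sprintf("%.12g", v),
                                ""), sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# lower bound on sigma = sqrt(sigma^2) supported by the parametrization
SIGMA_FLOOR <- 0.5

check_sigma_floor <- function(sigma) {
  if (any(sigma < SIGMA_FLOOR))
    stop(sprintf(
      "input standard deviation %.3g below the supported floor %.2g mV ms^-1/2",
      min(sigma), SIGMA_FLOOR))
  invisible(TRUE)
}
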