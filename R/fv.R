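#' Assemble the Scharfetter-Gummel finite-volume operator
#'
#' Builds the tridiagonal bands of the discrete drift-diffusion operator for
#' given total input moments.  Interior faces carry the exponentially fitted
#' Scharfetter-Gummel flux (centered differences recovered as the drift
#' vanishes, upwind flux for large drift); the lower boundary is reflecting
#' (zero flux), the upper absorbing via a ghost cell whose outflow
#' coefficient \code{w_out} maps the last cell density to the spike rate.
#'
#' @param grid a \code{\link{build_voltage_grid}} object
#' @param mu_tot total input mean (mV/ms)
#' @param sigma_tot_sq total input variance (mV^2/ms)
#' @param neuron a \code{\link{neuron_params}} object (already encoded in the
#'   grid's face drift; accepted for interface completeness)
#' @return an object of class \code{"fv_operator"} with bands \code{sub},
#'   \code{diag}, \code{sup} (1/ms) and outflow coefficient \code{w_out}
#'   (mV/ms)
#' @export
assemble_fv_operator <- function(grid, mu_tot, sigma_tot_sq, neuron = NULL) {
  stopifnot(inherits(grid, "voltage_grid"), sigma_tot_sq > 0)
  op <- cpp_fv_operator(grid$gface, mu_tot, sigma_tot_sq, grid$dV)
  op$grid <- grid
  op$mu_tot <- mu_tot
  op$sigma_tot_sq <- sigma_tot_sq
  class(op) <- "fv_operator"
  op
}

#' Fokker-Planck solver state
#'
#' Density per cell plus the refractory rate pipeline.
#' @param p density per cell (1/mV)
#' @param r_queue recent rate history (kHz), most recent last; length
#'   \code{n_ref}
#' @param t current time (ms)
#' @return an object of class \code{"fp_state"}
#' @export
fp_state <- function(p, r_queue = 0, t = 0) {
  structure(list(p = p, r_queue = r_queue, t = t), class = "fp_state")
}

#' One implicit finite-volume time step
#'
#' Solves \eqn{(I - \Delta t / \Delta V \; G)\,p^{n+1} = p^n + g} where
#' \eqn{g} reinjects the rate that left through the spike voltage one
#' refractory period ago into the reset cell.
#'
#' @param state an \code{\link{fp_state}}
#' @param op an \code{\link{assemble_fv_operator}} result
#' @param dt time step (ms)
#' @param reinjected_rate rate (kHz) reinjected this step, i.e. the outflow
#'   from \code{n_ref} steps earlier
#' @return updated \code{fp_state}; the new outflow rate is appended to the
#'   queue
#' @export
fv_step <- function(state, op, dt, reinjected_rate) {
  stopifnot(dt > 0)
  g <- op$grid
  p_new <- cpp_fv_step(state$p, op$sub, op$diag, op$sup, dt,
                       g$m_r - 1L, reinjected_rate, g$dV)
  r_new <- op$w_out * p_new[g$N_V]
  fp_state(p_new, c(state$r_queue, r_new), state$t + dt)
}

#' Instantaneous flux rate through the spike voltage
#'
#' Ghost-cell Scharfetter-Gummel outflow: \eqn{r = w_{out} \, p_{N_V}} with
#' the coefficients of the operator used for the last step.
#'
#' @param state an \code{\link{fp_state}}
#' @param op the operator used to advance the state
#' @return spike rate (kHz)
#' @export
flux_rate <- function(state, op) {
  stopifnot(op$w_out > 0)
  op$w_out * state$p[op$grid$N_V]
}

#' Integrate the Fokker-Planck mean-field model
#'
#' Time-dependent solution of the full mean-field system: per step the
#' total moments \eqn{\mu_{tot} = \mu_{syn} - \langle w \rangle / C},
#' \eqn{\sigma^2_{tot} = \sigma^2_{syn}} are formed from the external input
#' and the delayed rate, the Scharfetter-Gummel operator is rebuilt
#' (coefficients at \eqn{t_n}, implicit solve in the density), the rate is
#' read off the absorbing boundary flux, and the mean adaptation current and
#' delayed rate are advanced explicitly.
#'
#' @param neuron a \code{\link{neuron_params}} object
#' @param coupling a \code{\link{coupling_params}} object
#' @param mu_ext external mean input, an \code{fp_signal} (mV/ms)
#' @param sigma_ext_sq external input variance, an \code{fp_signal}
#'   (mV^2/ms)
#' @param grid optional \code{\link{build_voltage_grid}}; default spacing
#'   0.028 mV
#' @param dt time step (ms)
#' @param T duration (ms); defaults to the signal span
#' @param p0 initial density (default \code{\link{initial_density}})
#' @param w0,rd0 initial mean adaptation (pA) and delayed rate (kHz)
#' @param rec_dt recording bin (ms); rates are bin averages
#' @param keep_rate also return the rate at full step resolution
#' @return an object of class \code{"population_trace"}: signals \code{rate}
#'   (kHz, bin-averaged), \code{mean_V} (mV), \code{mean_w} (pA), \code{r_d}
#'   (kHz), plus the final density and the worst probability-bookkeeping
#'   error
#' @export
run_fp <- function(neuron, coupling, mu_ext, sigma_ext_sq, grid = NULL,
                   dt = 0.05, T = NULL, p0 = NULL, w0 = 0, rd0 = 0,
                   rec_dt = 1, keep_rate = FALSE) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(coupling, "coupling_params"),
            inherits(mu_ext, "fp_signal"), inherits(sigma_ext_sq, "fp_signal"))
  if (is.null(grid)) grid <- build_voltage_grid(neuron)
  if (is.null(T)) T <- (length(mu_ext$values) - 1) * mu_ext$dt
  rec_every <- max(1L, round(rec_dt / dt))
  n_steps <- floor(T / dt)
  n_steps <- (n_steps %/% rec_every) * rec_every
  tt <- (0:(n_steps - 1)) * dt
  mu <- stats::approx(signal_times(mu_ext), mu_ext$values, xout = tt,
                      rule = 2)$y
  s2 <- stats::approx(signal_times(sigma_ext_sq), sigma_ext_sq$values,
                      xout = tt, rule = 2)$y
  check_sigma_floor(sqrt(min(s2)))
  if (is.null(p0)) p0 <- initial_density(grid, neuron)
  dk <- switch(coupling$delay_kind, none = 0L, exponential = 1L,
               identical = 2L)
  res <- cpp_run_fp(grid$gface, grid$dV, grid$V_lb, grid$m_r - 1L, p0, dt,
                    n_steps, mu, s2, coupling$K, coupling$J, dk,
                    coupling$tau_d, coupling$d, neuron$a, neuron$b,
                    neuron$tau_w, neuron$E_w, neuron$C, neuron$T_ref,
                    w0, rd0, rec_every, SIGMA_FLOOR^2, keep_rate)
  rec_dt_eff <- rec_every * dt
  out <- structure(list(
    rate = signal(res$rate, rec_dt_eff, rec_dt_eff / 2, "kHz"),
    mean_V = signal(res$mean_V, rec_dt_eff, rec_dt_eff, "mV"),
    mean_w = signal(res$mean_w, rec_dt_eff, rec_dt_eff, "pA"),
    r_d = signal(res$r_d, rec_dt_eff, rec_dt_eff, "kHz"),
    p_final = res$p_final, mass_err_max = res$mass_err_max,
    model = "fp"), class = "population_trace")
  if (keep_rate) out$rate_full <- signal(res$rate_full, dt, dt, "kHz")
  out
}

#' @export
print.population_trace <- function(x, ...) {
  r <- x$rate$values
  cat(sprintf("population trace (%s): %d bins of %g ms, mean rate %.4g kHz\n",
              x$model, length(r), x$rate$dt, mean(r)))
  invisible(x)
}
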