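#' Stationary solution of the finite-volume Fokker-Planck system
#'
#' Solves the steady state of the drift-diffusion operator with reinjection
#' directly (a bordered linear system: the one-dimensional nullspace of the
#' operator is pinned and renormalized so that the density mass plus the
#' refractory mass \eqn{r_\infty T_{ref}} equals one).  Returns the
#' steady-state spike rate \eqn{r_\infty(\mu,\sigma)}, density and
#' non-refractory mean membrane voltage \eqn{\langle V \rangle_\infty}.
#'
#' @param mu generic input mean (mV/ms)
#' @param sigma generic input standard deviation (mV ms^-1/2), at least the
#'   supported floor of 0.5
#' @param grid a \code{\link{build_voltage_grid}} object
#' @param neuron a \code{\link{neuron_params}} object
#' @return an object of class \code{"stationary_result"} with fields
#'   \code{p_inf} (1/mV), \code{r_inf} (kHz), \code{mean_V_inf} (mV) and
#'   \code{refractory_mass}
#' @export
solve_stationary <- function(mu, sigma, grid, neuron) {
  stopifnot(inherits(grid, "voltage_grid"), inherits(neuron, "neuron_params"))
  check_sigma_floor(sigma)
  res <- cpp_stationary(grid$gface, mu, sigma^2, grid$dV, grid$V_lb,
                        grid$m_r - 1L, neuron$T_ref)
  structure(list(p_inf = res$p, r_inf = res$r_inf,
                 mean_V_inf = res$mean_V_inf,
                 refractory_mass = res$refractory_mass,
                 mu = mu, sigma = sigma, grid = grid),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf(
    "stationary EIF population at mu = %g, sigma = %g: r_inf = %.5g kHz, <V>_inf = %.4f mV\n",
    x$mu, x$sigma, x$r_inf, x$mean_V_inf))
  invisible(x)
}

#' Finite-difference derivatives of a gridded quantity
#'
#' Central differences in the interior, one-sided at the edges, for a field
#' sampled on a rectangular (mu, sigma) grid (mu varies along rows).
#'
#' @param field numeric matrix, \code{length(mu_grid)} rows by
#'   \code{length(sigma_grid)} columns
#' @param x_grid grid of the axis along which to differentiate
#' @param axis 1 for mu (rows), 2 for sigma (columns)
#' @return matrix of the same shape
#' @export
fd_grid <- function(field, x_grid, axis = 1) {
  n <- length(x_grid)
  if (n < 3) stop("need at least 3 grid points per axis for derivatives")
  if (axis == 2) return(t(fd_grid(t(field), x_grid, axis = 1)))
  h <- diff(x_grid)
  out <- field
  out[1, ] <- (field[2, ] - field[1, ]) / h[1]
  out[n, ] <- (field[n, ] - field[n - 1, ]) / h[n - 1]
  if (n > 2) {
    num <- field[3:n, , drop = FALSE] - field[1:(n - 2), , drop = FALSE]
    out[2:(n - 1), ] <- num / (x_grid[3:n] - x_grid[1:(n - 2)])
  }
  out
}

#' Derivatives of the stationary quantities on a (mu, sigma) grid
#'
#' Computes the input-moment derivatives required by the reduced models:
#' \eqn{\partial_\mu r_\infty}, \eqn{\partial_\sigma r_\infty},
#' \eqn{\partial_{\sigma^2} r_\infty}, \eqn{\partial_\mu \langle V
#' \rangle_\infty} and \eqn{\partial_{\sigma^2} \langle V \rangle_\infty},
#' using central finite differences on the precompute grid; derivatives with
#' respect to the variance follow from the chain rule
#' \eqn{\partial_{\sigma^2} = \partial_\sigma / (2\sigma)}.
#'
#' @param r_inf,V_inf matrices on the grid (mu along rows)
#' @param mu_grid,sigma_grid axis values
#' @return named list of derivative matrices
#' @export
stationary_derivatives <- function(r_inf, V_inf, mu_grid, sigma_grid) {
  d_mu_r <- fd_grid(r_inf, mu_grid, 1)
  d_sg_r <- fd_grid(r_inf, sigma_grid, 2)
  d_mu_V <- fd_grid(V_inf, mu_grid, 1)
  d_sg_V <- fd_grid(V_inf, sigma_grid, 2)
  inv2s <- matrix(1 / (2 * sigma_grid), nrow = nrow(r_inf),
                  ncol = length(sigma_grid), byrow = TRUE)
  list(d_mu_r_inf = d_mu_r, d_sigma_r_inf = d_sg_r,
       d_sigma2_r_inf = d_sg_r * inv2s,
       d_mu_V_inf = d_mu_V, d_sigma2_V_inf = d_sg_V * inv2s)
}

#' Mean membrane voltage with the optional spike-shape extension
#'
#' With the spike shape enabled the voltage is assumed to traverse linearly
#' from \eqn{V_s} to \eqn{V_r} during the refractory period, so the
#' steady-state average runs over all neurons:
#' \deqn{\langle V \rangle_\infty = \int v\,p_\infty(v)\,dv +
#'   \Big(1 - \int p_\infty(v)\,dv\Big) \frac{V_r + V_s}{2}.}
#' Disabled, the non-refractory average is returned.
#'
#' @param res a \code{\link{solve_stationary}} result
#' @param neuron a \code{\link{neuron_params}} object
#' @param enabled logical
#' @return mean voltage (mV)
#' @export
spike_shape_mean_voltage <- function(res, neuron, enabled = FALSE) {
  if (!enabled) return(res$mean_V_inf)
  g <- res$grid
  int_vp <- sum(g$centers * res$p_inf) * g$dV
  mass <- sum(res$p_inf) * g$dV
  int_vp + (1 - mass) * (neuron$V_r + neuron$V_s) / 2
}
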