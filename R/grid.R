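#' Finite-volume voltage grid
#'
#' Discretizes the Fokker-Planck domain \eqn{[V_{lb}, V_s]} into \code{N_V}
#' equidistant cells.  Cell faces sit at \eqn{V_{lb} + j\,dV}; the first and
#' last faces coincide with the reflecting and absorbing boundaries.  The
#' membrane drift \eqn{g(V) = [I_L(V) + I_{exp}(V)]/C} is precomputed at the
#' faces.
#'
#' @param neuron a \code{\link{neuron_params}} object
#' @param N_V number of cells; alternatively give \code{dV}
#' @param dV target cell width (mV); \code{N_V = round((V_s - V_lb)/dV)}
#' @return an object of class \code{"voltage_grid"} with centers, spacing and
#'   the index \code{m_r} of the cell containing the reset voltage
#' @export
build_voltage_grid <- function(neuron, N_V = NULL, dV = 0.028) {
  stopifnot(inherits(neuron, "neuron_params"))
  span <- neuron$V_s - neuron$V_lb
  if (is.null(N_V)) N_V <- round(span / dV)
  if (N_V < 10) stop("N_V must be at least 10")
  if (!(neuron$V_r > neuron$V_lb && neuron$V_r < neuron$V_s))
    stop("V_r must lie strictly inside (V_lb, V_s)")
  dV <- span / N_V
  centers <- neuron$V_lb + (seq_len(N_V) - 0.5) * dV
  faces <- neuron$V_lb + (0:N_V) * dV
  m_r <- findInterval(neuron$V_r, faces, rightmost.closed = TRUE)
  gface <- eif_drift_r(faces, neuron)
  structure(list(V_lb = neuron$V_lb, V_s = neuron$V_s, N_V = as.integer(N_V),
                 dV = dV, centers = centers, m_r = as.integer(m_r),
                 gface = gface), class = "voltage_grid")
}

# membrane drift g(V) in mV/ms (vectorized)
eif_drift_r <- function(V, neuron) {
  (-neuron$g_L * (V - neuron$E_L) +
     neuron$g_L * neuron$Delta_T * exp((V - neuron$V_T) / neuron$Delta_T)) /
    neuron$C
}

#' Node grid for the spectral sweeps
#'
#' Uniform voltage nodes \eqn{V_k = V_{lb} + k\,dV} used by the backward
#' (eigenflux) and forward (adjoint) exponential integrators.  The spacing is
#' adjusted so that both the reset and spike voltages fall exactly on nodes;
#' the reinjection discontinuity is applied at the reset node.
#'
#' @param neuron a \code{\link{neuron_params}} object
#' @param dV target node spacing (mV)
#' @return an object of class \code{"sweep_grid"}
#' @export
spectral_grid <- function(neuron, dV = 0.01) {
  span <- neuron$V_s - neuron$V_lb
  n_cells <- round(span / dV)
  # force the reset voltage onto a node
  k_r <- round((neuron$V_r - neuron$V_lb) / span * n_cells)
  n_low <- k_r
  n_cells <- n_low + round((neuron$V_s - neuron$V_r) / (span / n_cells))
  dV <- span / n_cells
  nodes <- neuron$V_lb + (0:n_cells) * dV
  k_r <- which.min(abs(nodes - neuron$V_r)) - 1L # 0-based
  g_mid <- eif_drift_r((nodes[-1] + nodes[-length(nodes)]) / 2, neuron)
  structure(list(n = n_cells + 1L, dV = dV, nodes = nodes,
                 k_r = as.integer(k_r), g_mid = g_mid),
            class = "sweep_grid")
}

#' Default initial membrane voltage density
#'
#' The Gaussian used to initialize the network simulator (mean
#' \eqn{V_r - \delta V}, standard deviation \eqn{\delta V / 2} with
#' \eqn{\delta V = V_T - V_r}), truncated to \eqn{[V_{lb}, V_s]},
#' discretized at the cell centers and renormalized.
#'
#' @param grid a \code{\link{build_voltage_grid}} object
#' @param neuron a \code{\link{neuron_params}} object
#' @return numeric density per cell (1/mV), summing to 1/dV
#' @export
initial_density <- function(grid, neuron) {
  dv0 <- neuron$V_T - neuron$V_r
  p <- stats::dnorm(grid$centers, mean = neuron$V_r - dv0, sd = dv0 / 2)
  p / (sum(p) * grid$dV)
}
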