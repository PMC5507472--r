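# Shared fixtures, built once per test run.  The quantity table uses a
# coarsened grid (mu step 0.1, sweep spacing 0.02 mV) so the whole suite
# stays fast; accuracy-critical checks construct their own fine grids.

.fx <- new.env(parent = emptyenv())

np_default <- function() neuron_params()
np_noadapt <- function() neuron_params(a = 0, b = 0)

test_table <- function() {
  if (is.null(.fx$tab)) {
    gs <- grid_spec(mu_min = -2, mu_max = 6.2, d_mu = 0.1,
                    sigma_min = 1.0, sigma_max = 2.0, d_sigma = 0.5)
    .fx$tab <- suppressWarnings(
      precompute_quantities(np_default(), gs, dV = 0.02, dV_sweep = 0.02))
  }
  .fx$tab
}

fine_fv_grid <- function() {
  if (is.null(.fx$fvg)) .fx$fvg <- build_voltage_grid(np_default(), dV = 0.01)
  .fx$fvg
}

fine_sweep_grid <- function() {
  if (is.null(.fx$sg)) .fx$sg <- spectral_grid(np_default(), dV = 0.01)
  .fx$sg
}

const_signals <- function(mu, sigma2, T, dt = 1) {
  n <- floor(T / dt) + 1
  list(mu = signal(rep(mu, n), dt), s2 = signal(rep(sigma2, n), dt))
}

# sparse finite-volume operator (with reinjection) as a Matrix, for
# independent eigenvalue cross-checks
fv_sparse_operator <- function(mu, sigma, neuron, dV = 0.01) {
  g <- build_voltage_grid(neuron, dV = dV)
  op <- assemble_fv_operator(g, mu, sigma^2)
  n <- g$N_V
  Matrix::sparseMatrix(
    i = c(2:n, 1:n, 1:(n - 1), g$m_r),
    j = c(1:(n - 1), 1:n, 2:n, n),
    x = c(op$sub[2:n], op$diag, op$sup[1:(n - 1)], op$w_out / g$dV),
    dims = c(n, n))
}

# leading eigenvalues of the sparse operator by real shift-invert Arnoldi
fv_operator_eigs <- function(mu, sigma, neuron, dV = 0.01, nev = 6,
                             shift = 0.02) {
  A <- fv_sparse_operator(mu, sigma, neuron, dV)
  n <- nrow(A)
  M <- A - Matrix::Diagonal(n, shift)
  f <- function(x, extra = NULL) as.numeric(Matrix::solve(M, x))
  res <- igraph::arpack(f, options = list(n = n, nev = nev,
                                          ncv = 3 * nev + 2, which = "LM",
                                          maxiter = 3000),
                        sym = FALSE, complex = TRUE)
  v <- 1 / res$values + shift
  v[order(-Re(v))]
}

# amplitude of a rate series over the third and fourth quarter of a run,
# for limit-cycle stationarity checks
osc_amplitudes <- function(r) {
  n <- length(r)
  c(diff(range(r[(n %/% 2):(n %/% 4 * 3)])),
    diff(range(r[(n %/% 4 * 3):n])))
}
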