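# linear rate response spectra and the semi-analytic filter fits

make_synthetic_spec <- function(R_mu, f, r_inf = 0.03, sigma0 = 1.5) {
  structure(list(f = f, R_mu = R_mu, R_sigma = R_mu, R_sigma2 = R_mu,
                 r_inf = r_inf, mu0 = 1, sigma0 = sigma0, Delta_T = 1.5),
            class = "response_spectrum")
}

test_that("least-squares exponential fit recovers a synthetic Lorentzian exactly", {
  f <- 10^seq(-3, 0, length.out = 64)
  tau_true <- 10
  spec <- make_synthetic_spec(0.04 / (1 + 2i * pi * f * tau_true), f)
  tau <- fit_exp_filter(spec, 0.04, mode = "least_squares")
  expect_equal(tau, tau_true, tolerance = 1e-6)
  expect_error(fit_exp_filter(spec, -0.1), "nonpositive")
})

test_that("damped-oscillator fit recovers synthetic parameters and reduces to the exponential at omega = 0", {
  f <- 10^seq(-3, 0, length.out = 64)
  tau_true <- 8; om_true <- 0.5
  spec <- make_synthetic_spec(0.05 * fprate:::dos_tf(f, tau_true, om_true), f)
  fit <- fit_dos_filter(spec, 0.05)
  expect_lt(abs(fit$tau / tau_true - 1), 0.02)
  expect_lt(abs(fit$omega / om_true - 1), 0.02)
  expect_equal(fit$B_mu, (1 + fit$tau^2 * fit$omega^2) / fit$tau)
  # omega = 0 target degenerates to the Lorentzian; B_mu = 1/tau
  spec0 <- make_synthetic_spec(0.05 / (1 + 2i * pi * f * 12), f)
  fit0 <- fit_dos_filter(spec0, 0.05)
  expect_lt(fit0$omega, 0.02)
  expect_lt(abs(fit0$tau / 12 - 1), 0.05)
  expect_equal(fprate:::dos_tf(f, 12, 0), fprate:::lorentzian_tf(f, 12))
})

test_that("sigma filter fit returns the Lorentzian time constant or the delta limit", {
  f <- 10^seq(-3, 0, length.out = 64)
  spec <- make_synthetic_spec(0.01 / (1 + 2i * pi * f * 5), f)
  spec$R_sigma <- spec$R_mu
  expect_equal(fit_sigma_filter(spec, 0.01), 5, tolerance = 1e-6)
  expect_equal(fit_sigma_filter(spec, -0.002), 0)
  expect_equal(fit_sigma_filter(spec, 0), 0)
})

test_that("zero-frequency response equals the stationary derivative", {
  np <- np_noadapt()
  g <- fine_fv_grid()
  spec <- linear_rate_response(1.5, 2.0, c(1e-5, 1e-4), g, np)
  h <- 1e-3
  dmu <- (solve_stationary(1.5 + h, 2.0, g, np)$r_inf -
            solve_stationary(1.5 - h, 2.0, g, np)$r_inf) / (2 * h)
  expect_lt(abs(Re(spec$R_mu[1]) / dmu - 1), 0.01)
  dsg <- (solve_stationary(1.5, 2.0 + h, g, np)$r_inf -
            solve_stationary(1.5, 2.0 - h, g, np)$r_inf) / (2 * h)
  expect_lt(abs(Re(spec$R_sigma[1]) / dsg - 1), 0.01)
})

test_that("asymptotic and least-squares time constants are consistent across regimes", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.02)
  h <- 0.01
  both <- function(mu, sg) {
    spec <- linear_rate_response(mu, sg, grid = g, neuron = np)
    dmu <- (solve_stationary(mu + h, sg, g, np)$r_inf -
              solve_stationary(mu - h, sg, g, np)$r_inf) / (2 * h)
    c(lsq = fit_exp_filter(spec, dmu, "least_squares"),
      asy = fit_exp_filter(spec, dmu, "asymptotic"))
  }
  # mean-driven regime: the response is tail-dominated and the two estimates
  # agree closely
  md <- both(2.5, 0.6)
  expect_lt(abs(md["lsq"] / md["asy"] - 1), 0.3)
  # fluctuation-dominated regime: the full fit follows the slow dominant
  # decay (close to 1/|Re lambda_1|) and exceeds the tail-matched estimate
  fd <- both(0.5, 3.5)
  expect_gt(fd["lsq"], fd["asy"])
  sgrid <- spectral_grid(np, dV = 0.02)
  tr <- track_spectrum(seq(-1.5, 0.5, by = 0.05), 3.5, sgrid, np)
  sel <- fprate:::select_lam12(tr$eigs[[length(tr$eigs)]])
  ratio <- fd["lsq"] * abs(Re(sel$lam1))
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2.0)
})

test_that("mean-driven points yield an oscillatory filter", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.02)
  spec <- linear_rate_response(2.5, 0.6, grid = g, neuron = np)
  h <- 0.01
  dmu <- (solve_stationary(2.5 + h, 0.6, g, np)$r_inf -
            solve_stationary(2.5 - h, 0.6, g, np)$r_inf) / (2 * h)
  fit <- fit_dos_filter(spec, dmu)
  expect_gt(fit$omega, 0.05)
})

test_that("fitted time constants stay within the sanity envelope on sample nodes", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.05)
  for (node in list(c(0.5, 1.5), c(2, 1.0), c(3.5, 2.5))) {
    spec <- linear_rate_response(node[1], node[2], grid = g, neuron = np)
    h <- 0.01
    dmu <- (solve_stationary(node[1] + h, node[2], g, np)$r_inf -
              solve_stationary(node[1] - h, node[2], g, np)$r_inf) / (2 * h)
    tl <- fit_exp_filter(spec, dmu)
    expect_gt(tl, 0); expect_lt(tl, 100)
    fit <- fit_dos_filter(spec, dmu)
    expect_gt(fit$tau, 0); expect_lt(fit$tau, 100)
  }
})
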