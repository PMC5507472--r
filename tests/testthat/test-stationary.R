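# steady-state spike rate, mean voltage, derivatives, spike-shape option

test_that("hyperpolarized steady state sits at the drift fixed point with negligible rate", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.02)
  st <- solve_stationary(-3, 0.5, g, np)
  expect_lt(st$r_inf, 1e-4)
  # stable branch of g(V) + mu = 0
  fx <- uniroot(function(V) fprate:::eif_drift_r(V, np) + (-3),
                c(np$V_lb, np$V_T))$root
  expect_lt(abs(st$mean_V_inf - fx), 1)
})

test_that("stationary density is normalized including the refractory mass", {
  np <- neuron_params(a = 0, b = 0, T_ref = 1.5)
  g <- build_voltage_grid(np, dV = 0.02)
  st <- solve_stationary(2.5, 1.5, g, np)
  expect_gt(st$refractory_mass, 0)
  expect_lt(abs(sum(st$p_inf) * g$dV + st$r_inf * np$T_ref - 1), 1e-10)
  expect_true(all(st$p_inf >= -1e-12))
})

test_that("steady-state rate is strictly increasing in the input mean", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.05)
  for (sg in c(0.5, 1.5, 3.0)) {
    r <- vapply(seq(-1, 4, by = 0.25),
                function(m) solve_stationary(m, sg, g, np)$r_inf, 0)
    # strict growth wherever the rate is above the numerical floor
    live <- r > 1e-10
    expect_true(all(diff(r[live]) > 0))
    expect_true(all(r >= 0))
  }
})

test_that("rate has a sharp threshold near rheobase at small noise", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.05)
  r_lo <- solve_stationary(0.2, 0.5, g, np)$r_inf
  r_hi <- solve_stationary(1.4, 0.5, g, np)$r_inf
  expect_lt(r_lo, 1e-5)
  expect_gt(r_hi, 0.01)
})

test_that("finite-difference grid derivatives are exact on affine fields", {
  mu <- seq(0, 2, by = 0.25)
  sg <- seq(0.5, 2, by = 0.25)
  f <- outer(mu, sg, function(m, s) 2 * m)
  d <- fd_grid(f, mu, axis = 1)
  expect_equal(d, matrix(2, length(mu), length(sg)))
  g2 <- outer(mu, sg, function(m, s) 3 * s - 1)
  expect_equal(fd_grid(g2, sg, axis = 2),
               matrix(3, length(mu), length(sg)))
  expect_error(fd_grid(f[1:2, ], mu[1:2], axis = 1), "3 grid points")
})

test_that("sigma^2 derivatives follow from the chain rule", {
  mu <- seq(0, 1, by = 0.5)
  sg <- c(1, 2, 3)
  r <- outer(mu, sg, function(m, s) s^2) # r = sigma^2 so d r/d sigma^2 = 1
  d <- stationary_derivatives(r, r, mu, sg)
  expect_equal(d$d_sigma2_r_inf[, 2], rep(1, 3), tolerance = 1e-12)
})

test_that("rate loses sigma sensitivity in the mean-driven corner", {
  np <- np_noadapt()
  g <- build_voltage_grid(np, dV = 0.02)
  h <- 0.02
  dsg <- (solve_stationary(4, 0.5 + h, g, np)$r_inf -
            solve_stationary(4, 0.5, g, np)$r_inf) / h
  expect_lt(dsg, 0) # negative derivative triggers the tau_sigma -> 0 fallback
})

test_that("spike-shape extension shifts the mean voltage toward the spike trajectory", {
  np <- neuron_params(a = 0, b = 0, T_ref = 1.5)
  g <- build_voltage_grid(np, dV = 0.05)
  st <- solve_stationary(3, 1.5, g, np)
  plain <- spike_shape_mean_voltage(st, np, enabled = FALSE)
  expect_equal(plain, st$mean_V_inf)
  ext <- spike_shape_mean_voltage(st, np, enabled = TRUE)
  # direct algebra on the stored density
  int_vp <- sum(g$centers * st$p_inf) * g$dV
  mass <- sum(st$p_inf) * g$dV
  expect_equal(ext, int_vp + (1 - mass) * (np$V_r + np$V_s) / 2,
               tolerance = 1e-12)
  # with zero refractory mass both variants coincide
  np0 <- np_noadapt()
  g0 <- build_voltage_grid(np0, dV = 0.05)
  st0 <- solve_stationary(3, 1.5, g0, np0)
  expect_equal(spike_shape_mean_voltage(st0, np0, TRUE),
               sum(g0$centers * st0$p_inf) * g0$dV, tolerance = 1e-12)
})

test_that("voltage grid construction honors the reset cell and spacing", {
  np <- np_default()
  g <- build_voltage_grid(np, N_V = 10)
  expect_equal(g$dV, (np$V_s - np$V_lb) / 10)
  expect_equal(diff(g$centers), rep(g$dV, 9))
  expect_equal(g$centers[1] - g$dV / 2, np$V_lb)
  expect_equal(g$centers[10] + g$dV / 2, np$V_s)
  faces <- np$V_lb + (0:10) * g$dV
  expect_true(faces[g$m_r] <= np$V_r && np$V_r <= faces[g$m_r + 1])
  # Table-like spacing gives the expected cell count
  g2 <- build_voltage_grid(np, dV = 0.028)
  expect_equal(g2$N_V, round((np$V_s - np$V_lb) / 0.028))
  expect_error(build_voltage_grid(neuron_params(), N_V = 5), "N_V")
})
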