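# the four reduced rate models and their shared dynamics

test_that("mean adaptation update has the right trivial behavior and fixed point", {
  np <- neuron_params(a = 0, b = 0)
  expect_equal(step_mean_adaptation(0, -60, 0.05, np, 0.1), 0)
  np2 <- neuron_params(a = 4, b = 40)
  # relaxation toward a(V - E_w) with b = 0
  np3 <- neuron_params(a = 4, b = 0)
  w <- 0
  for (k in 1:40000) w <- step_mean_adaptation(w, -60, 0, np3, 0.05)
  expect_equal(w, 4 * (-60 + 80), tolerance = 1e-4)
  # fixed point with constant rate: a(V - E_w) + tau_w b r
  wstar <- np2$a * (-60 - np2$E_w) + np2$tau_w * np2$b * 0.02
  f <- (np2$a * (-60 - np2$E_w) - wstar) / np2$tau_w + np2$b * 0.02
  expect_equal(f, 0)
  # exponential decay time constant tau_w (log-slope of the b = 0 relaxation)
  w0 <- 100; dt <- 0.05
  traj <- numeric(2000); w <- w0
  for (k in 1:2000) { w <- step_mean_adaptation(w, np3$E_w, 0, np3, dt); traj[k] <- w }
  tt <- (1:2000) * dt
  slope <- coef(lm(log(traj) ~ tt))[2]
  expect_equal(as.numeric(slope), -1 / np3$tau_w, tolerance = 1e-3)
})

test_that("delayed rate matches the exponential-kernel convolution", {
  cp <- coupling_params(K = 10, J = 0.1, delay_kind = "exponential", tau_d = 4)
  dt <- 0.01
  n <- 4000
  r <- c(1 / dt, rep(0, n - 1)) # discrete impulse
  rd <- numeric(n); x <- 0
  for (k in 1:n) { x <- step_delayed_rate(x, r[k], cp, dt); rd[k] <- x }
  tt <- (1:n) * dt
  kernel <- exp(-tt / cp$tau_d) / cp$tau_d
  expect_lt(max(abs(rd - kernel)) / max(kernel), 0.01)
  # constant input relaxes with tau_d
  x <- 0; for (k in 1:2000) x <- step_delayed_rate(x, 0.05, cp, dt)
  expect_equal(x, 0.05 * (1 - exp(-2000 * dt / 4)), tolerance = 1e-3)
  # identical delays read the buffer; no delays pass through
  cpi <- coupling_params(K = 10, J = 0.1, delay_kind = "identical", d = 5)
  buf <- seq(0.01, 0.1, length.out = 10)
  expect_equal(step_delayed_rate(0, 0.2, cpi, dt = 1, r_buffer = buf),
               buf[6])
  cpn <- coupling_params(K = 10, J = 0.1, delay_kind = "none")
  expect_equal(step_delayed_rate(0.3, 0.2, cpn, dt = 1), 0.2)
})

test_that("all models sit exactly on the stationary rate under constant input", {
  tab <- test_table()
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  sig <- const_signals(2, 4, T = 400)
  ri <- lookup(tab, 2, 2, "r_inf")$r_inf
  for (m in c("spec1", "spec2", "lnexp", "lndos")) {
    tr <- run_rate_model(m, tab, np, cp, sig$mu, sig$s2, T = 400)
    expect_lt(max(abs(tail(tr$rate$values, 100) - ri)) / ri, 1e-6)
  }
})

test_that("spec1 relaxes at the dominant eigenvalue rate after a small step", {
  tab <- test_table()
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  # pick a node where lambda_1 is real (pure exponential relaxation)
  j <- which(tab$sigma == 2.0)
  real_idx <- which(tab$arrays$lam1_im[, j] == 0 &
                      tab$arrays$r_inf[, j] > 2e-4)
  i <- real_idx[length(real_idx)]
  mu1 <- tab$mu[i]
  mu0 <- mu1 - 0.1
  tt <- seq(0, 500, 0.5)
  mu_sig <- gaussian_smooth(signal(ifelse(tt < 200, mu0, mu1), 0.5), 1)
  s2_sig <- signal(rep(4, length(tt)), 0.5)
  tr <- run_rate_model("spec1", tab, np, cp, mu_sig, s2_sig, T = 500,
                       rec_dt = 0.5)
  ri <- tab$arrays$r_inf[i, j]
  lam <- tab$arrays$lam1_re[i, j]
  t_r <- signal_times(tr$rate)
  seg <- t_r > 215 & t_r < 215 + 2 / abs(lam)
  dev <- abs(tr$rate$values[seg] - ri)
  slope <- coef(lm(log(dev) ~ t_r[seg]))[2]
  expect_lt(abs(abs(slope) / abs(lam) - 1), 0.05)
})

test_that("spec2 rings at the eigenvalue frequency and clamps negative excursions", {
  tab <- test_table()
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  tt <- seq(0, 500, 0.5)
  mu_sig <- gaussian_smooth(signal(ifelse(tt < 200, 2, 2.1), 0.5), 1)
  s2_sig <- signal(rep(4, length(tt)), 0.5)
  tr <- run_rate_model("spec2", tab, np, cp, mu_sig, s2_sig, T = 500,
                       rec_dt = 0.5)
  ri2 <- lookup(tab, 2.1, 2, "r_inf")$r_inf
  l1 <- complex(real = lookup(tab, 2.1, 2, "lam1_re")$lam1_re,
                imaginary = lookup(tab, 2.1, 2, "lam1_im")$lam1_im)
  t_r <- signal_times(tr$rate)
  seg <- t_r > 210 & t_r < 250
  y <- tr$rate$values[seg] - ri2
  zc <- which(diff(sign(y)) != 0)
  expect_gt(length(zc), 2)
  freq <- 1 / (2 * mean(diff(t_r[seg][zc])))
  expect_lt(abs(freq / (abs(Im(l1)) / (2 * pi)) - 1), 0.15)
  # a violent downward step drives the clamp; the output stays nonnegative
  mu_dn <- gaussian_smooth(signal(ifelse(tt < 200, 2.5, -1), 0.5), 1)
  tr2 <- run_rate_model("spec2", tab, np, cp, mu_dn, s2_sig, T = 500)
  expect_gt(tr2$n_clamped, 0)
  expect_true(all(tr2$rate$values >= 0))
})

test_that("spec2 refuses unsupported configurations", {
  tab <- test_table()
  cp_id <- coupling_params(K = 100, J = 0.05, delay_kind = "identical", d = 2)
  sig <- const_signals(2, 4, T = 10)
  np_ref <- neuron_params(T_ref = 2)
  expect_error(run_rate_model("spec2", tab, np_ref, coupling_params(K = 0),
                              sig$mu, sig$s2, T = 10), "refractory")
  expect_error(run_rate_model("spec2", tab, np_noadapt(), cp_id,
                              sig$mu, sig$s2, T = 10), "exponential delays")
})

test_that("LN_exp tracks the stationary nonlinearity for quasi-static input", {
  tab <- test_table()
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  mu_sig <- ou_input(ou_params(mean = 2.5, theta = 0.3, tau_ou = 500,
                               sigma_t = 1), 0.5, 4000, seed = 31)
  s2_sig <- signal(rep(4, length(mu_sig$values)), 0.5)
  tr <- run_rate_model("lnexp", tab, np, cp, mu_sig, s2_sig, T = 4000)
  t_r <- signal_times(tr$rate)
  mu_at <- approx(signal_times(mu_sig), mu_sig$values, xout = t_r)$y
  r_qs <- vapply(mu_at, function(m) lookup(tab, m, 2, "r_inf")$r_inf, 0)
  keep <- t_r > 500
  expect_lt(max(abs(tr$rate$values[keep] - r_qs[keep])) / mean(r_qs[keep]),
            0.02)
})

test_that("LN_dos with a zeroed oscillator table matches LN_exp's construction at fixed points", {
  tab <- test_table()
  tab0 <- tab
  tab0$arrays$omega[] <- 0
  tab0$arrays$tau <- tab$arrays$tau_mu
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  sig <- const_signals(2.5, 2.25, T = 300)
  trd <- run_rate_model("lndos", tab0, np, cp, sig$mu, sig$s2, T = 300)
  tre <- run_rate_model("lnexp", tab, np, cp, sig$mu, sig$s2, T = 300)
  expect_equal(tail(trd$rate$values, 50), tail(tre$rate$values, 50),
               tolerance = 1e-8)
})

test_that("LN_dos shows resonant amplification near the filter frequency", {
  tab <- test_table()
  np <- np_noadapt()
  cp <- coupling_params(K = 0)
  om <- lookup(tab, 3.5, 1.0, "omega")$omega
  expect_gt(om, 0.05) # mean-driven corner is oscillatory
  f_res <- om / (2 * pi)
  gain_at <- function(f0) {
    tt <- seq(0, 1500, 0.05)
    eps <- 0.02
    mu_sig <- signal(3.5 + eps * sin(2 * pi * f0 * tt), 0.05)
    s2_sig <- signal(rep(1.0, length(tt)), 0.05)
    tr <- run_rate_model("lndos", tab, np, cp, mu_sig, s2_sig, T = 1500,
                         rec_dt = 0.2)
    t_r <- signal_times(tr$rate)
    keep <- t_r > 500
    y <- tr$rate$values[keep]; tk <- t_r[keep]
    X <- cbind(sin(2 * pi * f0 * tk), cos(2 * pi * f0 * tk))
    cf <- coef(lm(y ~ X))
    sqrt(cf[2]^2 + cf[3]^2) / eps
  }
  expect_gt(gain_at(f_res), 1.2 * gain_at(f_res / 8))
})

test_that("Heun halving shows second-order self-convergence where Euler is first order", {
  # a synthetic table with globally affine quantity fields makes the model
  # right-hand side smooth (bilinear interpolation of affine data is exact),
  # so the stepper's order is measurable without interpolation kinks
  np <- np_default()
  mu_g <- seq(-1, 5, by = 0.5)
  sg_g <- c(1, 2, 3)
  aff <- function(a0, am) outer(mu_g, sg_g, function(m, s) a0 + am * m)
  cst <- function(v) matrix(v, length(mu_g), length(sg_g))
  tab <- structure(list(
    mu = mu_g, sigma = sg_g,
    arrays = list(r_inf = aff(0.02, 0.006), mean_V_inf = aff(-58, 1),
                  lam1_re = cst(-0.1), lam1_im = cst(0.4),
                  lam2_re = cst(-0.1), lam2_im = cst(-0.4),
                  M = cst(0.03), S = cst(5e-4), F_mu = cst(0.003),
                  F_sigma2 = cst(4e-4), d_mu_V_inf = cst(1),
                  d_sigma2_V_inf = cst(0), d_mu_r_inf = cst(0.006),
                  d_sigma_r_inf = cst(0), tau_mu = cst(5),
                  tau_sigma = cst(3), tau = cst(5), omega = cst(0.3)),
    neuron = np, hash = fprate:::params_hash(np),
    meta = list(masked = 0L)), class = "quantity_table")
  cp <- coupling_params(K = 0)
  tt <- seq(0, 200, 0.5)
  mu_sig <- signal(2 + 0.5 * sin(2 * pi * tt / 50), 0.5)
  s2_sig <- signal(rep(4, length(tt)), 0.5)
  # compare the adaptation trace, which is recorded instantaneously at the
  # same times for every dt (the bin-averaged rate is itself an O(dt)
  # quadrature and would mask the stepper order)
  run_dt <- function(dt, method) run_rate_model("spec2", tab, np, cp, mu_sig,
                                                s2_sig, dt = dt, T = 200,
                                                method = method)$mean_w$values
  h1 <- run_dt(0.04, "heun"); h2 <- run_dt(0.02, "heun"); h3 <- run_dt(0.01, "heun")
  eh1 <- max(abs(h1 - h2)); eh2 <- max(abs(h2 - h3))
  expect_gt(eh1 / eh2, 2^1.8)
  e1 <- run_dt(0.04, "euler"); e2 <- run_dt(0.02, "euler"); e3 <- run_dt(0.01, "euler")
  ee1 <- max(abs(e1 - e2)); ee2 <- max(abs(e2 - e3))
  expect_lt(ee1 / ee2, 3)
  expect_gt(ee1 / ee2, 1.4)
})

test_that("model outputs are nonnegative across random inputs", {
  tab <- test_table()
  np <- np_default()
  cp <- coupling_params(K = 0)
  mu_sig <- ou_input(ou_params(mean = 1, theta = 1, tau_ou = 20, sigma_t = 1),
                     0.5, 2000, seed = 77)
  s2_sig <- signal(rep(2.25, length(mu_sig$values)), 0.5)
  for (m in c("spec1", "spec2", "lnexp", "lndos")) {
    tr <- run_rate_model(m, tab, np, cp, mu_sig, s2_sig, T = 2000)
    expect_true(all(tr$rate$values >= 0), info = m)
  }
})

test_that("a mismatched table is rejected", {
  tab <- test_table()
  np_other <- neuron_params(Delta_T = 2)
  sig <- const_signals(2, 4, T = 10)
  expect_error(run_rate_model("lnexp", tab, np_other, coupling_params(K = 0),
                              sig$mu, sig$s2, T = 10), "different neuron")
})
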