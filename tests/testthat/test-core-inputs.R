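# parameter containers, OU input generation, smoothing, synaptic moments

test_that("parameter constructors validate their invariants", {
  expect_error(neuron_params(V_r = -40), "ordering")
  expect_error(neuron_params(Delta_T = 0))
  expect_error(coupling_params(K = -1))
  expect_error(coupling_params(K = 10, delay_kind = "exponential", tau_d = 0))
  expect_error(ou_params(tau_ou = -1))
  expect_s3_class(neuron_params(), "neuron_params")
})

test_that("noiseless OU process is its fixed point and seeds reproduce", {
  p <- ou_params(mean = 2.5, theta = 0, tau_ou = 50)
  x <- ou_process(p, dt = 0.5, T = 100, seed = 4)
  expect_true(all(x$values == 2.5))
  p2 <- ou_params(mean = 1, theta = 0.5, tau_ou = 50)
  a <- ou_process(p2, dt = 0.1, T = 500, seed = 11)
  b <- ou_process(p2, dt = 0.1, T = 500, seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         ou_process(p2, dt = 0.1, T = 500, seed = 12)$values))
})

test_that("OU samples match the stationary law and autocovariance", {
  tau <- 50; theta <- 0.8; m <- 1.5
  p <- ou_params(mean = m, theta = theta, tau_ou = tau)
  x <- ou_process(p, dt = 1, T = 4e5, seed = 99)$values
  # batch-means standard error for the mean of an OU series
  se_mean <- theta * sqrt(2 * tau / (length(x) * 1))
  expect_lt(abs(mean(x) - m), 4 * se_mean)
  expect_lt(abs(sd(x) - theta) / theta, 0.05)
  lag <- 50 # samples = tau_ou at dt = 1
  ac <- cor(x[-(1:lag)], x[1:(length(x) - lag)])
  expect_lt(abs(ac - exp(-1)), 0.03)
})

test_that("OU process rejects unresolvable steps", {
  expect_error(ou_process(ou_params(tau_ou = 1), dt = 1, T = 10, seed = 1),
               "tau_ou")
  expect_error(ou_process(ou_params(tau_ou = 50), dt = -1, T = 10, seed = 1))
})

test_that("Gaussian smoothing preserves constants and affine trends, and is linear", {
  s_const <- signal(rep(3, 200), 0.5)
  expect_equal(gaussian_smooth(s_const, 2)$values, rep(3, 200))
  # interior of a linear ramp is unchanged by a symmetric kernel
  ramp <- signal(seq(0, 10, length.out = 401), 0.5)
  sm <- gaussian_smooth(ramp, 1.5)
  interior <- 30:370
  expect_equal(sm$values[interior], ramp$values[interior], tolerance = 1e-10)
  # unit impulse maps to the sampled kernel (truncated at 4 sigma)
  imp <- signal(c(rep(0, 100), 1, rep(0, 100)), 0.5)
  smi <- gaussian_smooth(imp, 1.5)
  hw <- ceiling(4 * 1.5 / 0.5)
  kk <- rep(0, 201)
  kern <- dnorm(seq(-hw, hw) * 0.5, sd = 1.5)
  kk[101 + (-hw:hw)] <- kern / sum(kern)
  expect_equal(smi$values, kk, tolerance = 1e-12)
  # linearity
  set.seed(1)
  x <- signal(rnorm(300), 0.5); y <- signal(rnorm(300), 0.5)
  lin <- gaussian_smooth(signal(2 * x$values - 3 * y$values, 0.5), 1)
  sep <- 2 * gaussian_smooth(x, 1)$values - 3 * gaussian_smooth(y, 1)$values
  expect_equal(lin$values, sep, tolerance = 1e-12)
  # sigma_t = 0 returns the input unchanged
  expect_identical(gaussian_smooth(x, 0)$values, x$values)
})

test_that("synaptic moments combine external and recurrent input", {
  cp <- coupling_params(K = 100, J = 0.05, delay_kind = "exponential",
                        tau_d = 3)
  m <- synaptic_moments(1.5, 2.25, r_d = 0, coupling = cp)
  expect_equal(m$mu_syn, 1.5)
  expect_equal(m$sigma_syn_sq, 2.25)
  m0 <- synaptic_moments(1.5, 2.25, r_d = 0.04, coupling_params(K = 0))
  expect_equal(m0$mu_syn, 1.5)
  # inhibition lowers the mean but still raises the variance
  cpi <- coupling_params(K = 100, J = -0.05, delay_kind = "exponential")
  mi <- synaptic_moments(1.5, 2.25, r_d = 0.04, cpi)
  expect_lt(mi$mu_syn, 1.5)
  expect_gt(mi$sigma_syn_sq, 2.25)
  # monotone in r_d
  rd <- seq(0, 0.2, by = 0.02)
  ms <- synaptic_moments(1.5, 2.25, rd, cpi)
  expect_true(all(diff(ms$sigma_syn_sq) > 0))
  expect_error(synaptic_moments(1.5, 2.25, -0.1, cpi), "nonnegative")
})

test_that("signal CSV export roundtrips values", {
  x <- signal(sin(1:50), 0.25, units = "kHz")
  f <- tempfile(fileext = ".csv")
  write_signal_csv(x, f)
  d <- read.csv(f, comment.char = "#")
  expect_equal(d$value, x$values)
  expect_equal(d$t, signal_times(x))
})
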