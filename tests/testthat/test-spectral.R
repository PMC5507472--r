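# eigenvalue shooting solver, adjoint problem, biorthonormalization

test_that("the stationary eigenvalue is an exact root of the lower-bound flux", {
  np <- np_default()
  sg <- fine_sweep_grid()
  for (node in list(c(1.5, 2.0), c(0.5, 1.0), c(3.0, 1.5))) {
    fn <- fprate:::make_flux_fn(node[1], node[2], sg, np)
    root <- uniroot(function(l) Re(fn(complex(real = l))),
                    c(-0.02, 0.02), tol = 1e-13)$root
    expect_lt(abs(root), 1e-8)
  }
})

test_that("real scan finds distinct negative eigenvalues, OU-like when hyperpolarized", {
  np <- np_default()
  sg <- fine_sweep_grid()
  roots <- init_spectrum_real_scan(-1.5, 2.0, sg, np, n_eigs = 5)
  expect_true(all(roots < 0))
  expect_true(all(diff(roots) < 0)) # sorted decreasing, distinct
  # far below threshold the EIF reduces to an OU process with membrane time
  # constant C/g_L, whose spectrum is -n g_L / C
  tau_m <- np$C / np$g_L
  expect_equal(roots, -(1:5) / tau_m, tolerance = 0.02)
})

test_that("lower-bound flux is conjugate-symmetric in lambda", {
  np <- np_default()
  sg <- spectral_grid(np, dV = 0.05)
  lam <- complex(real = -0.2, imaginary = 0.3)
  a <- backward_flux(lam, 1.0, 1.5, sg, np)
  b <- backward_flux(Conj(lam), 1.0, 1.5, sg, np)
  expect_equal(a$q_lb, Conj(b$q_lb), tolerance = 1e-12)
  expect_equal(a$log_scale, b$log_scale)
})

test_that("adjoint eigenfunction at lambda = 0 is the constant unit function", {
  np <- np_default()
  sg <- fine_sweep_grid()
  ad <- solve_adjoint(0 + 0i, 1.5, 2.0, sg, np)
  expect_lt(max(Mod(ad$psi - 1)), 1e-6)
  expect_lt(ad$resid_rel, 1e-8)
})

test_that("adjoint eigenfunction of the dominant mode is C1 at the reset", {
  np <- np_default()
  sg <- fine_sweep_grid()
  path <- seq(-1.5, 1.5, by = 0.05)
  tr <- track_spectrum(path, 1.5, sg, np, n_track = 4)
  sel <- fprate:::select_lam12(tr$eigs[[length(path)]])
  ad <- solve_adjoint(sel$lam1, 1.5, 1.5, sg, np)
  expect_lt(ad$resid_rel, 1e-6)
  k <- sg$k_r + 1 # R index of the reset node
  d_below <- (ad$psi[k] - ad$psi[k - 1]) / sg$dV
  d_above <- (ad$psi[k + 1] - ad$psi[k]) / sg$dV
  scale <- max(Mod(c(d_below, d_above)))
  expect_lt(Mod(d_above - d_below) / scale, 0.01)
})

test_that("biorthonormalization scales pairs to unit product with small cross terms", {
  np <- np_default()
  sg <- fine_sweep_grid()
  mu <- 2.0; sigma <- 1.5
  path <- seq(-1.5, mu, by = 0.05)
  tr <- track_spectrum(path, sigma, sg, np, n_track = 4)
  eigs <- tr$eigs[[length(path)]]
  sel <- fprate:::select_lam12(eigs)
  ph <- fprate:::phi0_sweep(mu, sigma, sg, np)
  sols <- list(list(lam = 0 + 0i, phi = ph$phi0,
                    q = c(rep(0, sg$k_r), rep(ph$r_inf, sg$n - sg$k_r)),
                    psi = rep(1 + 0i, sg$n)))
  bf <- backward_flux(sel$lam1, mu, sigma, sg, np, want_fun = TRUE)
  ad <- solve_adjoint(sel$lam1, mu, sigma, sg, np)
  sols[[2]] <- list(lam = sel$lam1, phi = bf$phi * exp(bf$log_scale),
                    q = bf$q * exp(bf$log_scale), psi = ad$psi)
  out <- biorthonormalize(sols, sg$dV)
  for (s in out)
    expect_lt(Mod(fprate:::inner_prod(s$psi, s$phi, sg$dV) - 1), 1e-8)
  cross <- attr(out, "cross")
  expect_lt(Mod(cross[1, 2]), 1e-4)
  expect_lt(Mod(cross[2, 1]), 1e-4)
  # downstream flux-times-projection products are invariant under a joint
  # rescale phi -> c phi, psi -> psi / c (the bilinear combination that
  # enters the rate models)
  s2 <- sols[[2]]
  cc <- 3.7 - 1.1i
  s2$phi <- s2$phi * cc; s2$q <- s2$q * cc; s2$psi <- s2$psi / cc
  out2 <- biorthonormalize(list(sols[[1]], s2), sg$dV)
  gfun <- sin(seq(0, 3, length.out = sg$n)) # arbitrary test function
  prod_a <- out[[2]]$q[sg$n] * fprate:::inner_prod(out[[2]]$psi, gfun, sg$dV)
  prod_b <- out2[[2]]$q[sg$n] * fprate:::inner_prod(out2[[2]]$psi, gfun, sg$dV)
  expect_equal(prod_a, prod_b, tolerance = 1e-10)
})

test_that("tracked spectra show the documented branch phenomenology", {
  np <- np_default()
  sg <- spectral_grid(np, dV = 0.02)
  path <- seq(-1.5, 4, by = 0.05)
  tr <- track_spectrum(path, 1.5, sg, np, n_track = 5)
  sel <- lapply(tr$eigs, fprate:::select_lam12)
  l1 <- vapply(sel, function(s) s$lam1, complex(1))
  # all real parts nonpositive
  all_re <- unlist(lapply(tr$eigs, Re))
  expect_lt(max(all_re), 1e-9)
  # after the real-to-complex merge the imaginary part grows almost linearly
  im <- Im(l1)
  on <- which(im > 0)
  expect_gt(length(on), 20)
  seg <- on[-(1:5)]
  fit <- lm(im[seg] ~ path[seg])
  rel_resid <- sqrt(mean(residuals(fit)^2)) / mean(im[seg])
  expect_lt(rel_resid, 0.05)
  expect_gt(coef(fit)[2], 0)
  # at large sigma a real (diffusive) eigenvalue persists across the range
  tr2 <- track_spectrum(seq(-1.5, 2, by = 0.05), 2.0, sg, np, n_track = 5)
  has_real <- vapply(tr2$eigs, function(e) any(abs(Im(e)) < 1e-9), TRUE)
  expect_true(all(has_real))
})

test_that("stationary eigenfunction from the sweep matches the finite-volume density", {
  np <- np_default()
  sg <- fine_sweep_grid()
  g <- fine_fv_grid()
  ph <- fprate:::phi0_sweep(1.5, 2.0, sg, np)
  st <- solve_stationary(1.5, 2.0, g, np)
  expect_lt(abs(ph$r_inf / st$r_inf - 1), 2e-3)
  p_sweep <- approx(sg$nodes, ph$phi0, xout = g$centers)$y
  expect_lt(max(abs(p_sweep - st$p_inf)) / max(st$p_inf), 5e-3)
})

test_that("refractory reinjection shifts the dominant eigenvalue", {
  np <- neuron_params(a = 0, b = 0, T_ref = 2)
  sg <- spectral_grid(np, dV = 0.02)
  fn0 <- fprate:::make_flux_fn(1.5, 1.5, sg, np, refr_mode = FALSE)
  fnr <- fprate:::make_flux_fn(1.5, 1.5, sg, np, refr_mode = TRUE)
  # lambda_0 = 0 remains an exact root with refractoriness
  r0 <- fprate:::newton_root(fnr, complex(real = -0.01))
  expect_lt(abs(r0$lam), 1e-8)
  path <- seq(-1.5, 1.5, by = 0.05)
  tr <- track_spectrum(path, 1.5, sg, np, n_track = 4, refr_mode = TRUE)
  sel <- fprate:::select_lam12(tr$eigs[[length(path)]])
  tr2 <- track_spectrum(path, 1.5, sg, np, n_track = 4, refr_mode = FALSE)
  sel2 <- fprate:::select_lam12(tr2$eigs[[length(path)]])
  expect_gt(Mod(sel$lam1 - sel2$lam1), 1e-4)
  expect_lt(Re(sel$lam1), 0)
})

test_that("eigenflux coefficient matrix has the stated structure", {
  np <- np_default()
  A0 <- coefficient_matrix(-60, 0 + 0i, 1.5, 4, np)
  expect_equal(A0[1, ], c(0 + 0i, 0 + 0i)) # lambda = 0: flux is conserved
  # at V_T the exponential current contributes exactly g_L Delta_T / C
  A <- coefficient_matrix(np$V_T, -0.1 + 0i, 0, 2, np)
  g_at_VT <- (-np$g_L * (np$V_T - np$E_L) + np$g_L * np$Delta_T) / np$C
  expect_equal(A[2, 2], -2 * g_at_VT / 2 + 0i)
  # real for real lambda
  expect_true(all(Im(coefficient_matrix(-55, -0.3 + 0i, 1, 2, np)) == 0))
})
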