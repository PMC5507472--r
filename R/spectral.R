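# Spectral decomposition of the Fokker-Planck operator: eigenvalues via a
# backward shooting formulation (the lower-bound eigenflux must vanish),
# eigenfunctions of the operator and its adjoint via exponential (one-term
# Magnus) integration, and the lumped scalar quantities entering the
# spectral rate models.

#' Lower-bound eigenflux for an eigenvalue candidate
#'
#' Integrates the first-order system for (eigenflux, eigenfunction) backward
#' from the spike voltage (absorbing condition, unit flux) through the reset
#' (reinjection jump) to the lower bound.  A vanishing returned flux
#' identifies \code{lam} as an eigenvalue of the Fokker-Planck operator.
#'
#' @param lam complex eigenvalue candidate (1/ms)
#' @param mu,sigma generic input moments
#' @param sgrid a \code{\link{spectral_grid}}
#' @param neuron a \code{\link{neuron_params}} object
#' @param refr_mode apply the refractory reinjection factor
#'   \eqn{e^{-\lambda T_{ref}}}
#' @param want_fun also return the eigenfunction and eigenflux on the grid
#' @return list with \code{q_lb} (complex, at the internal checkpoint scale),
#'   \code{log_scale}, and optionally \code{phi}, \code{q}
#' @export
backward_flux <- function(lam, mu, sigma, sgrid, neuron, refr_mode = FALSE,
                          want_fun = FALSE) {
  check_sigma_floor(sigma)
  r <- cpp_backward_flux(Re(lam), Im(lam), sgrid$g_mid, sgrid$dV, mu,
                         sigma^2, sgrid$k_r, neuron$T_ref, refr_mode,
                         want_fun)
  out <- list(q_lb = complex(real = r$q_lb_re, imaginary = r$q_lb_im),
              log_scale = r$log_scale)
  if (want_fun) { out$phi <- r$phi; out$q <- r$q }
  out
}

# closure returning the (relative-scale reconstructed) lower-bound flux as a
# smooth complex function of lambda, for Newton iteration
make_flux_fn <- function(mu, sigma, sgrid, neuron, refr_mode = FALSE) {
  ref <- NULL
  function(lam) {
    r <- cpp_backward_flux(Re(lam), Im(lam), sgrid$g_mid, sgrid$dV, mu,
                           sigma^2, sgrid$k_r, neuron$T_ref, refr_mode,
                           FALSE)
    if (is.null(ref)) ref <<- r$log_scale
    complex(real = r$q_lb_re, imaginary = r$q_lb_im) *
      exp(r$log_scale - ref)
  }
}

# damped complex Newton iteration with finite-difference derivative; real
# seeds with a real-valued flux stay on the real axis
newton_root <- function(fn, lam0, tol = 1e-11, maxit = 60) {
  lam <- lam0
  f <- fn(lam)
  for (it in seq_len(maxit)) {
    h <- 1e-7 * (1 + abs(lam))
    fp <- (fn(lam + h) - f) / h
    if (!is.finite(abs(fp)) || abs(fp) == 0)
      return(list(lam = lam, ok = FALSE))
    step <- f / fp
    lam_new <- lam - step
    f_new <- fn(lam_new)
    k <- 0
    while ((!is.finite(abs(f_new)) || abs(f_new) > 2 * abs(f)) && k < 6) {
      step <- step / 2
      lam_new <- lam - step
      f_new <- fn(lam_new)
      k <- k + 1
    }
    conv <- abs(step) < tol * (1 + abs(lam_new))
    lam <- lam_new
    f <- f_new
    if (conv) return(list(lam = lam, ok = TRUE, f = f, iters = it))
  }
  list(lam = lam, ok = FALSE, f = f, iters = maxit)
}

#' Real eigenvalue scan at strongly hyperpolarizing mean input
#'
#' For sufficiently small mean input all eigenvalues are real; they are the
#' roots of the one-dimensional map \eqn{\lambda \mapsto q(V_{lb}; \lambda)}.
#' The scan brackets sign changes on a dense grid in \eqn{[-L, 0)} (widening
#' \eqn{L} adaptively until enough roots are found) and refines each by
#' bisection.  The stationary root \eqn{\lambda_0 = 0} is excluded.
#'
#' @param mu_min hyperpolarizing mean input (mV/ms)
#' @param sigma input standard deviation
#' @param sgrid,neuron grid and neuron parameters
#' @param n_eigs number of nonstationary eigenvalues requested
#' @param lam_window initial scan depth (1/ms)
#' @param n_scan scan density per window
#' @param refr_mode refractory reinjection factor
#' @return numeric vector of real eigenvalues, sorted by decreasing value
#'   (dominant first)
#' @export
init_spectrum_real_scan <- function(mu_min, sigma, sgrid, neuron,
                                    n_eigs = 4, lam_window = 1.5,
                                    n_scan = 600, refr_mode = FALSE) {
  check_sigma_floor(sigma)
  roots <- numeric(0)
  L <- lam_window
  for (attempt in 1:5) {
    lams <- seq(-L, -1e-5, length.out = n_scan)
    sc <- cpp_scan_real(lams, sgrid$g_mid, sgrid$dV, mu_min, sigma^2,
                        sgrid$k_r, neuron$T_ref, refr_mode)
    qv <- sc[, 1]
    sgn <- sign(qv)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(idx) >= n_eigs || attempt == 5) {
      fn <- make_flux_fn(mu_min, sigma, sgrid, neuron, refr_mode)
      roots <- vapply(idx, function(i) {
        r <- stats::uniroot(function(l) Re(fn(complex(real = l))),
                            lower = lams[i], upper = lams[i + 1],
                            tol = 1e-12)
        r$root
      }, 0)
      roots <- sort(roots, decreasing = TRUE)
      if (length(roots) >= n_eigs) return(roots[seq_len(n_eigs)])
      if (attempt == 5) break
    }
    L <- 2 * L
    n_scan <- round(n_scan * 1.6)
  }
  if (length(roots) < n_eigs)
    stop(sprintf("found only %d real eigenvalues in [-%g, 0); spectrum may not be all-real at mu = %g",
                 length(roots), L, mu_min))
  roots
}

#' Continue eigenvalue branches along a path of mean inputs
#'
#' Tracks the leading nonstationary eigenvalues from a hyperpolarized
#' starting point, where the spectrum is real, along increasing mean input.
#' Real branches are followed by Newton continuation; when two real branches
#' collide they are replaced by a single complex representative (with
#' nonnegative imaginary part) of the conjugate pair that forms at the
#' real-to-complex transition.  On failure the mean-input step is refined
#' internally.
#'
#' @param mu_path increasing mean-input values; the first entry must be
#'   hyperpolarized enough for an all-real spectrum
#' @param sigma input standard deviation
#' @param sgrid,neuron grid and neuron parameters
#' @param n_track number of branches to track
#' @param refr_mode refractory reinjection factor
#' @return list with \code{eigs}, a \code{length(mu_path)} list of complex
#'   vectors (complex entries stand for a conjugate pair), and \code{flags},
#'   an integer vector counting unresolved branches per node
#' @export
track_spectrum <- function(mu_path, sigma, sgrid, neuron, n_track = 5,
                           refr_mode = FALSE) {
  start <- init_spectrum_real_scan(mu_path[1], sigma, sgrid, neuron,
                                   n_eigs = n_track, refr_mode = refr_mode)
  branches <- lapply(start, function(l) list(lam = complex(real = l),
                                             real = TRUE, dead = FALSE))
  eigs <- vector("list", length(mu_path))
  flags <- integer(length(mu_path))
  eigs[[1]] <- vapply(branches, function(b) b$lam, complex(1))
  same_root <- function(a, b) abs(a - b) < 1e-5 * (1 + abs(a))
  advance <- function(branches, mu_from, mu_to, depth = 0) {
    fn <- make_flux_fn(mu_to, sigma, sgrid, neuron, refr_mode)
    updated <- branches
    for (i in seq_along(branches)) {
      b <- branches[[i]]
      if (b$dead) next
      r <- newton_root(fn, b$lam)
      lam <- r$lam
      if (Im(lam) < 0) lam <- Conj(lam)
      # a continuation step should move the root only modestly; a long jump
      # means the branch was captured by a different root
      jumped <- abs(lam - b$lam) > 0.5 * (1 + abs(b$lam))
      if (!r$ok || jumped) { updated[[i]]$pending <- TRUE; next }
      if (b$real && abs(Im(lam)) < 1e-9) lam <- complex(real = Re(lam))
      updated[[i]]$lam <- lam
      updated[[i]]$real <- abs(Im(lam)) < 1e-9
      updated[[i]]$pending <- FALSE
    }
    live <- function() which(vapply(updated, function(b) !b$dead, TRUE))
    # deduplicate: when several branches land on one root, the branch whose
    # previous value was closest keeps it, the others lost their root
    for (i in live()) for (j in live()) {
      if (i >= j) next
      bi <- updated[[i]]; bj <- updated[[j]]
      if (isTRUE(bi$pending) || isTRUE(bj$pending)) next
      if (same_root(bi$lam, bj$lam)) {
        keep_i <- abs(branches[[i]]$lam - bi$lam) <=
          abs(branches[[j]]$lam - bj$lam)
        updated[[if (keep_i) j else i]]$pending <- TRUE
        updated[[if (keep_i) j else i]]$lam <-
          branches[[if (keep_i) j else i]]$lam
      }
    }
    # lost real branches merge pairwise into complex conjugate pairs
    repeat {
      pend <- which(vapply(updated, function(b)
        isTRUE(b$pending) && b$real && !b$dead, TRUE))
      if (length(pend) < 1) break
      i1 <- pend[1]
      # partner: the other lost real branch with the closest previous value
      if (length(pend) >= 2) {
        prev1 <- branches[[i1]]$lam
        rest <- pend[-1]
        d <- abs(vapply(branches[rest], function(b) b$lam, complex(1)) - prev1)
        i2 <- rest[which.min(d)]
        mid <- (Re(branches[[i1]]$lam) + Re(branches[[i2]]$lam)) / 2
        gap <- abs(Re(branches[[i1]]$lam) - Re(branches[[i2]]$lam))
        seed <- complex(real = mid, imaginary = max(gap, 0.02))
        r <- newton_root(fn, seed)
        dup <- FALSE
        if (r$ok) {
          lam <- if (Im(r$lam) < 0) Conj(r$lam) else r$lam
          for (k in live())
            if (!isTRUE(updated[[k]]$pending) && k != i1 && k != i2 &&
                same_root(lam, updated[[k]]$lam)) dup <- TRUE
        }
        if (r$ok && !dup && Im(r$lam) > 1e-7) {
          updated[[i1]]$lam <- lam
          updated[[i1]]$real <- FALSE
          updated[[i1]]$pending <- FALSE
          updated[[i2]]$dead <- TRUE
          updated[[i2]]$pending <- FALSE
          next
        }
      }
      # no partner or merge attempt failed: refine the mean-input step
      if (depth < 5) {
        mu_mid <- (mu_from + mu_to) / 2
        half1 <- advance(branches, mu_from, mu_mid, depth + 1)
        return(advance(half1, mu_mid, mu_to, depth + 1))
      }
      updated[[i1]]$pending <- FALSE
      updated[[i1]]$dead <- TRUE
    }
    if (any(vapply(updated, function(b)
      isTRUE(b$pending) && !b$dead, TRUE))) {
      if (depth < 5) {
        mu_mid <- (mu_from + mu_to) / 2
        half1 <- advance(branches, mu_from, mu_mid, depth + 1)
        return(advance(half1, mu_mid, mu_to, depth + 1))
      }
      for (i in seq_along(updated))
        if (isTRUE(updated[[i]]$pending)) updated[[i]]$dead <- TRUE
    }
    updated
  }
  for (k in 2:length(mu_path)) {
    branches <- advance(branches, mu_path[k - 1], mu_path[k])
    live <- vapply(branches, function(b) !b$dead, TRUE)
    eigs[[k]] <- vapply(branches[live], function(b) b$lam, complex(1))
    flags[k] <- sum(!live)
  }
  list(eigs = eigs, flags = flags, mu_path = mu_path)
}

# dominant eigenvalue and its partner per the spectral model selection rules:
# lam1 minimizes |Re| over nonzero eigenvalues; lam2 minimizes |Re| over the
# remaining ones subject to lam1 + lam2 being real (conjugate partner if lam1
# is complex, next real eigenvalue if lam1 is real)
select_lam12 <- function(eigs) {
  ok <- abs(eigs) > 1e-9
  eigs <- eigs[ok]
  if (!length(eigs)) return(list(lam1 = NA_complex_, lam2 = NA_complex_))
  i1 <- which.min(abs(Re(eigs)))
  lam1 <- eigs[i1]
  if (abs(Im(lam1)) > 1e-9) return(list(lam1 = lam1, lam2 = Conj(lam1)))
  rest <- eigs[-i1]
  rest <- rest[abs(Im(rest)) < 1e-9]
  if (!length(rest)) return(list(lam1 = lam1, lam2 = NA_complex_))
  list(lam1 = lam1, lam2 = rest[which.min(abs(Re(rest)))])
}

#' Adjoint eigenfunction for a given eigenvalue
#'
#' Integrates the adjoint eigenproblem forward from the lower bound with
#' \eqn{\psi(V_{lb}) = 1}, \eqn{\psi'(V_{lb}) = 0} (reflecting condition) up
#' to the spike voltage; the derivative is continuous across the reset.  The
#' residual of the remaining boundary condition \eqn{\psi(V_s) =
#' \psi(V_r)\,e^{-\lambda T_{ref}}} measures how well \code{lam} solves the
#' adjoint problem; large residuals flag an inconsistent eigenvalue.
#'
#' @inheritParams backward_flux
#' @param tol residual tolerance (relative to the sup norm) above which a
#'   warning is emitted
#' @return list with the complex \code{psi} on the grid (normalized to
#'   \eqn{\psi(V_{lb}) = 1}) and the relative residual
#' @export
solve_adjoint <- function(lam, mu, sigma, sgrid, neuron, refr_mode = FALSE,
                          tol = 1e-3) {
  r <- cpp_solve_adjoint(Re(lam), Im(lam), sgrid$g_mid, sgrid$dV, mu,
                         sigma^2, sgrid$k_r, neuron$T_ref, refr_mode)
  psi <- r$psi / r$psi[1] # restore psi(V_lb) = 1 exactly
  if (r$resid_rel > tol)
    warning(sprintf("adjoint boundary residual %.2e at lambda = %s; eigenvalue may be inaccurate",
                    r$resid_rel, format(lam)))
  list(psi = psi, resid_rel = r$resid_rel)
}

# non-conjugated trapezoidal inner product on the sweep grid
inner_prod <- function(a, b, dV) {
  n <- length(a)
  w <- rep(1, n); w[1] <- 0.5; w[n] <- 0.5
  sum(w * a * b) * dV
}

#' Biorthonormalize forward/adjoint eigenfunction pairs
#'
#' Scales each forward eigenfunction so that the non-conjugated inner
#' product with its adjoint partner is one; the eigenflux is scaled along.
#' Cross products between different modes are reported for diagnostics.
#'
#' @param solutions list of solutions, each a list with elements \code{lam},
#'   \code{phi}, \code{q} (on the sweep grid) and \code{psi}
#' @param dV grid spacing
#' @return the input list with \code{phi}, \code{q} rescaled and a
#'   \code{cross} matrix of off-diagonal inner products attached as an
#'   attribute
#' @export
biorthonormalize <- function(solutions, dV) {
  ips <- vapply(solutions, function(s) inner_prod(s$psi, s$phi, dV),
                complex(1))
  if (any(abs(ips) < 1e-12))
    stop("degenerate forward/adjoint pairing (inner product ~ 0)")
  out <- Map(function(s, ip) {
    s$phi <- s$phi / ip
    s$q <- s$q / ip
    s$biorthonormalized <- TRUE
    s
  }, solutions, ips)
  n <- length(out)
  cross <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cross[i, j] <- inner_prod(out[[i]]$psi, out[[j]]$phi, dV)
  attr(out, "cross") <- cross
  out
}

# stationary eigenfunction phi_0 = p_inf on the sweep grid, from the lambda=0
# backward sweep, normalized so that the density mass plus r_inf T_ref is 1;
# returns the density and the spectral r_inf
phi0_sweep <- function(mu, sigma, sgrid, neuron) {
  b <- backward_flux(0 + 0i, mu, sigma, sgrid, neuron, want_fun = TRUE)
  phi <- Re(b$phi) * exp(b$log_scale)
  mass <- inner_prod(phi, rep(1, length(phi)), sgrid$dV)
  s <- 1 / (mass + neuron$T_ref) # q(V_s) = 1 before scaling
  list(phi0 = phi * s, r_inf = s)
}

# eigenfunction quantities for one selected eigenvalue: biorthonormalized
# eigenflux at V_s (f_n) and the couplings c_n^mu, c_n^sigma2 from the
# mu/sigma^2 derivatives of the adjoint eigenfunction projected on phi_0
node_eigen_quantities <- function(lam, mu, sigma, sgrid, neuron, phi0,
                                  h_mu = 0.005, h_s2_rel = 0.01) {
  bf <- backward_flux(lam, mu, sigma, sgrid, neuron, want_fun = TRUE)
  phi <- bf$phi # scaled by exp(-log_scale); q(V_s)_true = 1
  ad <- solve_adjoint(lam, mu, sigma, sgrid, neuron)
  ip <- inner_prod(ad$psi, phi, sgrid$dV) * exp(bf$log_scale)
  f_n <- 1 / ip # q_{phi_n}(V_s) after biorthonormal scaling of phi_n
  # local stencil in mu
  psi_at <- function(mu_s, sigma_s, seed) {
    fn <- make_flux_fn(mu_s, sigma_s, sgrid, neuron)
    r <- newton_root(fn, seed)
    if (!r$ok) stop("eigenvalue polish failed on derivative stencil")
    solve_adjoint(r$lam, mu_s, sigma_s, sgrid, neuron)$psi
  }
  psi_mu_p <- psi_at(mu + h_mu, sigma, lam)
  psi_mu_m <- psi_at(mu - h_mu, sigma, lam)
  c_mu <- inner_prod((psi_mu_p - psi_mu_m) / (2 * h_mu), phi0, sgrid$dV)
  s2 <- sigma^2
  h_s2 <- h_s2_rel * s2
  psi_s_p <- psi_at(mu, sqrt(s2 + h_s2), lam)
  psi_s_m <- psi_at(mu, sqrt(s2 - h_s2), lam)
  c_s2 <- inner_prod((psi_s_p - psi_s_m) / (2 * h_s2), phi0, sgrid$dV)
  list(f = f_n, c_mu = c_mu, c_s2 = c_s2, resid = ad$resid_rel)
}

#' Spectral quantities at one point of the input-moment plane
#'
#' Computes everything the spectral rate models need at generic input
#' moments (mu, sigma): the two dominant eigenvalues (the partner chosen so
#' that their sum is real), the biorthonormalized eigenfluxes at the spike
#' voltage \eqn{f_n}, the adjoint couplings \eqn{c_n^{\mu} = \langle
#' \partial_\mu \psi_n, \phi_0\rangle}, \eqn{c_n^{\sigma^2}}, and the lumped
#' real scalars \eqn{M = \partial_\mu r_\infty + f\cdot c_\mu},
#' \eqn{S = \partial_{\sigma^2} r_\infty + f\cdot c_{\sigma^2}},
#' \eqn{F_\mu = f\cdot\Lambda c_\mu}, \eqn{F_{\sigma^2} =
#' f\cdot\Lambda c_{\sigma^2}}.
#'
#' @param mu,sigma generic input moments
#' @param sgrid,neuron grid and neuron parameters
#' @param eigs optional precomputed eigenvalue set at (mu, sigma); when
#'   missing the branches are tracked from \code{mu_start}
#' @param fv_grid optional finite-volume grid for the stationary derivatives
#'   (defaults to the sweep spacing)
#' @param mu_start hyperpolarized tracking start
#' @return an object of class \code{"spectral_quantities"}
#' @export
spectral_quantities <- function(mu, sigma, sgrid, neuron, eigs = NULL,
                                fv_grid = NULL, mu_start = -1.5) {
  if (is.null(eigs)) {
    mu0 <- min(mu_start, mu - 0.5)
    path <- seq(mu0, mu, length.out = max(2, ceiling((mu - mu0) / 0.05) + 1))
    tr <- track_spectrum(path, sigma, sgrid, neuron)
    eigs <- tr$eigs[[length(tr$eigs)]]
  }
  sel <- select_lam12(eigs)
  lam1 <- sel$lam1; lam2 <- sel$lam2
  if (is.na(lam1) || is.na(lam2))
    stop("could not select two dominant eigenvalues")
  ph <- phi0_sweep(mu, sigma, sgrid, neuron)
  # local stationary derivatives (finite-volume solves)
  if (is.null(fv_grid)) fv_grid <- build_voltage_grid(neuron, dV = sgrid$dV)
  dmu <- 0.01
  dsg <- 0.01
  rp <- cpp_stationary(fv_grid$gface, mu + dmu, sigma^2, fv_grid$dV,
                       fv_grid$V_lb, fv_grid$m_r - 1L, neuron$T_ref)
  rm <- cpp_stationary(fv_grid$gface, mu - dmu, sigma^2, fv_grid$dV,
                       fv_grid$V_lb, fv_grid$m_r - 1L, neuron$T_ref)
  sp <- cpp_stationary(fv_grid$gface, mu, (sigma + dsg)^2, fv_grid$dV,
                       fv_grid$V_lb, fv_grid$m_r - 1L, neuron$T_ref)
  sm <- cpp_stationary(fv_grid$gface, mu, (sigma - dsg)^2, fv_grid$dV,
                       fv_grid$V_lb, fv_grid$m_r - 1L, neuron$T_ref)
  dmu_r <- (rp$r_inf - rm$r_inf) / (2 * dmu)
  ds2_r <- (sp$r_inf - sm$r_inf) / (2 * dsg) / (2 * sigma)
  conj_pair <- abs(Im(lam1)) > 1e-9
  q1 <- node_eigen_quantities(lam1, mu, sigma, sgrid, neuron, ph$phi0)
  if (conj_pair) {
    f <- c(q1$f, Conj(q1$f))
    c_mu <- c(q1$c_mu, Conj(q1$c_mu))
    c_s2 <- c(q1$c_s2, Conj(q1$c_s2))
  } else {
    q2 <- node_eigen_quantities(lam2, mu, sigma, sgrid, neuron, ph$phi0)
    f <- c(q1$f, q2$f)
    c_mu <- c(q1$c_mu, q2$c_mu)
    c_s2 <- c(q1$c_s2, q2$c_s2)
  }
  lams <- c(lam1, lam2)
  f_cmu <- Re(sum(f * c_mu))
  f_cs2 <- Re(sum(f * c_s2))
  F_mu <- Re(sum(f * lams * c_mu))
  F_s2 <- Re(sum(f * lams * c_s2))
  structure(list(lam1 = lam1, lam2 = lam2, r_inf = ph$r_inf,
                 f = f, c_mu = c_mu, c_sigma2 = c_s2,
                 f_cmu = f_cmu, f_csigma2 = f_cs2,
                 F_mu = F_mu, F_sigma2 = F_s2,
                 M = dmu_r + f_cmu, S = ds2_r + f_cs2,
                 d_mu_r_inf = dmu_r, d_sigma2_r_inf = ds2_r,
                 mu = mu, sigma = sigma),
            class = "spectral_quantities")
}

#' @export
print.spectral_quantities <- function(x, ...) {
  cat(sprintf("spectral quantities at (mu = %g, sigma = %g):\n", x$mu, x$sigma))
  cat(sprintf("  lam1 = %s, lam2 = %s (1/ms), r_inf = %.5g kHz\n",
              format(x$lam1, digits = 4), format(x$lam2, digits = 4),
              x$r_inf))
  cat(sprintf("  M = %.4g, S = %.4g, F_mu = %.4g, F_sigma2 = %.4g\n",
              x$M, x$S, x$F_mu, x$F_sigma2))
  invisible(x)
}

#' Coefficient matrix of the eigenflux first-order system
#'
#' The eigenproblem of the Fokker-Planck operator is equivalent to
#' \deqn{-\frac{d}{dV}\begin{pmatrix} q_\phi \\ \phi \end{pmatrix} =
#'   \begin{pmatrix} 0 & \lambda \\ 2/\sigma^2 & -2(g(V)+\mu)/\sigma^2
#'   \end{pmatrix}\begin{pmatrix} q_\phi \\ \phi \end{pmatrix}}
#' with the membrane drift \eqn{g(V) = [I_L(V) + I_{exp}(V)]/C}.  The
#' backward Magnus integrator exponentiates this matrix at cell midpoints.
#'
#' @param V voltage (mV)
#' @param lam complex eigenvalue candidate (1/ms)
#' @param mu input mean (mV/ms)
#' @param sigma_sq input variance (mV^2/ms)
#' @param neuron a \code{\link{neuron_params}} object
#' @return complex 2x2 matrix
#' @export
coefficient_matrix <- function(V, lam, mu, sigma_sq, neuron) {
  stopifnot(sigma_sq > 0)
  g <- eif_drift_r(V, neuron)
  matrix(c(0 + 0i, 2 / sigma_sq + 0i,
           as.complex(lam), -2 * (g + mu) / sigma_sq + 0i),
         2, 2)
}
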