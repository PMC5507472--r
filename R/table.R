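# Precomputation of all (mu, sigma)-dependent quantities on a rectangular
# grid, persistence, and bilinear interpolation during time integration.

#' Input-moment grid specification
#'
#' @param mu_min,mu_max,d_mu mean-input axis (mV/ms); default spacing 0.025
#' @param sigma_min,sigma_max,d_sigma noise axis (mV ms^-1/2); default
#'   spacing 0.1; \code{sigma_min} may not be below the supported floor 0.5
#' @return an object of class \code{"grid_spec"}
#' @export
grid_spec <- function(mu_min = -1.5, mu_max = 5, d_mu = 0.025,
                      sigma_min = 0.5, sigma_max = 5, d_sigma = 0.1) {
  stopifnot(d_mu > 0, d_sigma > 0, mu_max > mu_min, sigma_max > sigma_min)
  if (sigma_min < SIGMA_FLOOR)
    stop("sigma_min below the supported floor 0.5 mV ms^-1/2")
  mu <- seq(mu_min, mu_max, by = d_mu)
  sigma <- seq(sigma_min, sigma_max, by = d_sigma)
  if (length(mu) < 3 || length(sigma) < 3)
    stop("need at least 3 grid points per axis")
  structure(list(mu = mu, sigma = sigma), class = "grid_spec")
}

#' Precompute the quantity table
#'
#' Fills the (mu, sigma) grid with every input-moment dependent quantity the
#' reduced models need: stationary rate and mean voltage with their
#' derivatives; the two dominant eigenvalues of the Fokker-Planck operator
#' together with the lumped spectral scalars (M, S, F_mu, F_sigma2); and the
#' cascade filter parameters (tau_mu, tau_sigma, tau, omega).  The table is
#' keyed by the neuron parameters only: changing input, coupling or
#' adaptation parameters requires no recomputation.
#'
#' Spectral branches are continued along mu per sigma column, starting from a
#' hyperpolarized mean input where the spectrum is real.  Nodes where the
#' eigenvalue solve fails are filled by interpolation along mu and counted in
#' the metadata.
#'
#' @param neuron a \code{\link{neuron_params}} object
#' @param gridspec a \code{\link{grid_spec}}
#' @param which subset of \code{c("stationary", "spectral", "cascade")}
#' @param dV finite-volume spacing for stationary/cascade solves (mV)
#' @param dV_sweep node spacing of the spectral sweeps (mV)
#' @param n_freq size of the frequency grid for the cascade fits
#' @param verbose print per-column progress
#' @return an object of class \code{"quantity_table"}
#' @export
precompute_quantities <- function(neuron, gridspec,
                                  which = c("stationary", "spectral",
                                            "cascade"),
                                  dV = 0.01, dV_sweep = 0.01, n_freq = 48,
                                  verbose = FALSE) {
  stopifnot(inherits(neuron, "neuron_params"), inherits(gridspec, "grid_spec"))
  which <- match.arg(which, several.ok = TRUE)
  mu_g <- gridspec$mu
  sg_g <- gridspec$sigma
  nm <- length(mu_g); ns <- length(sg_g)
  fvg <- build_voltage_grid(neuron, dV = dV)
  M0 <- function() matrix(NA_real_, nm, ns)
  arr <- list(r_inf = M0(), mean_V_inf = M0())
  masked <- 0L

  # --- stationary quantities ------------------------------------------------
  for (j in seq_len(ns)) for (i in seq_len(nm)) {
    st <- cpp_stationary(fvg$gface, mu_g[i], sg_g[j]^2, fvg$dV, fvg$V_lb,
                         fvg$m_r - 1L, neuron$T_ref)
    arr$r_inf[i, j] <- st$r_inf
    arr$mean_V_inf[i, j] <- st$mean_V_inf
  }
  der <- stationary_derivatives(arr$r_inf, arr$mean_V_inf, mu_g, sg_g)
  arr <- c(arr, der)

  # --- spectral quantities --------------------------------------------------
  if ("spectral" %in% which) {
    sgrid <- spectral_grid(neuron, dV = dV_sweep)
    for (nm_q in c("lam1_re", "lam1_im", "lam2_re", "lam2_im", "f_cmu",
                   "f_csigma2", "F_mu", "F_sigma2", "M", "S"))
      arr[[nm_q]] <- M0()
    mu_start <- min(-1.5, mu_g[1])
    pre <- if (mu_start < mu_g[1])
      seq(mu_start, mu_g[1], by = min(0.05, diff(mu_g)[1]))[-1] else numeric(0)
    path <- c(mu_start, pre[-length(pre)], mu_g)
    first_idx <- length(path) - nm + 1
    for (j in seq_len(ns)) {
      t0 <- Sys.time()
      tr <- track_spectrum(path, sg_g[j], sgrid, neuron)
      for (i in seq_len(nm)) {
        eigs <- tr$eigs[[first_idx + i - 1]]
        sel <- select_lam12(eigs)
        if (is.na(sel$lam1) || is.na(sel$lam2)) { masked <- masked + 1L; next }
        arr$lam1_re[i, j] <- Re(sel$lam1); arr$lam1_im[i, j] <- Im(sel$lam1)
        arr$lam2_re[i, j] <- Re(sel$lam2); arr$lam2_im[i, j] <- Im(sel$lam2)
        qn <- tryCatch(
          node_quantities_at(sel, mu_g[i], sg_g[j], sgrid, neuron, fvg),
          error = function(e) NULL)
        if (is.null(qn)) { masked <- masked + 1L; next }
        arr$f_cmu[i, j] <- qn$f_cmu
        arr$f_csigma2[i, j] <- qn$f_csigma2
        arr$F_mu[i, j] <- qn$F_mu
        arr$F_sigma2[i, j] <- qn$F_sigma2
        arr$M[i, j] <- qn$M
        arr$S[i, j] <- qn$S
      }
      if (verbose)
        message(sprintf("spectral column sigma = %.3g done in %.1f s",
                        sg_g[j],
                        as.numeric(Sys.time() - t0, units = "secs")))
    }
    for (nm_q in c("lam1_re", "lam1_im", "lam2_re", "lam2_im", "f_cmu",
                   "f_csigma2", "F_mu", "F_sigma2", "M", "S"))
      arr[[nm_q]] <- fill_masked(arr[[nm_q]])
  }

  # --- cascade quantities ---------------------------------------------------
  if ("cascade" %in% which) {
    for (nm_q in c("tau_mu", "tau_mu_asym", "tau_sigma", "tau", "omega"))
      arr[[nm_q]] <- M0()
    f_grid <- 10^seq(-3, 0, length.out = n_freq)
    h <- 0.01
    for (j in seq_len(ns)) {
      t0 <- Sys.time()
      for (i in seq_len(nm)) {
        spec <- linear_rate_response(mu_g[i], sg_g[j], f_grid, fvg, neuron)
        rp <- cpp_stationary(fvg$gface, mu_g[i] + h, sg_g[j]^2, fvg$dV,
                             fvg$V_lb, fvg$m_r - 1L, neuron$T_ref)$r_inf
        rm <- cpp_stationary(fvg$gface, mu_g[i] - h, sg_g[j]^2, fvg$dV,
                             fvg$V_lb, fvg$m_r - 1L, neuron$T_ref)$r_inf
        sp <- cpp_stationary(fvg$gface, mu_g[i], (sg_g[j] + h)^2, fvg$dV,
                             fvg$V_lb, fvg$m_r - 1L, neuron$T_ref)$r_inf
        sm <- cpp_stationary(fvg$gface, mu_g[i], (sg_g[j] - h)^2, fvg$dV,
                             fvg$V_lb, fvg$m_r - 1L, neuron$T_ref)$r_inf
        dmu_r <- (rp - rm) / (2 * h)
        dsg_r <- (sp - sm) / (2 * h)
        if (dmu_r > 1e-10) {
          # quiescent nodes (rate numerically zero) leave the normalization
          # undefined; they are filled from the nearest responsive node below
          arr$tau_mu[i, j] <- fit_exp_filter(spec, dmu_r, "least_squares")
          arr$tau_mu_asym[i, j] <- fit_exp_filter(spec, dmu_r, "asymptotic")
          dos <- fit_dos_filter(spec, dmu_r)
          arr$tau[i, j] <- dos$tau
          arr$omega[i, j] <- dos$omega
        }
        arr$tau_sigma[i, j] <- fit_sigma_filter(spec, dsg_r)
      }
      if (verbose)
        message(sprintf("cascade column sigma = %.3g done in %.1f s",
                        sg_g[j],
                        as.numeric(Sys.time() - t0, units = "secs")))
    }
    for (nm_q in c("tau_mu", "tau_mu_asym", "tau", "omega"))
      arr[[nm_q]] <- fill_masked(arr[[nm_q]])
  }

  structure(list(mu = mu_g, sigma = sg_g, arrays = arr, neuron = neuron,
                 hash = params_hash(neuron),
                 meta = list(which = which, dV = dV, dV_sweep = dV_sweep,
                             masked = masked,
                             version = as.character(utils::packageVersion("fprate")))),
            class = "quantity_table")
}

# per-node spectral scalars for the selected eigenvalue pair
node_quantities_at <- function(sel, mu, sigma, sgrid, neuron, fvg) {
  ph <- phi0_sweep(mu, sigma, sgrid, neuron)
  dmu <- 0.01; dsg <- 0.01
  rp <- cpp_stationary(fvg$gface, mu + dmu, sigma^2, fvg$dV, fvg$V_lb,
                       fvg$m_r - 1L, neuron$T_ref)$r_inf
  rm <- cpp_stationary(fvg$gface, mu - dmu, sigma^2, fvg$dV, fvg$V_lb,
                       fvg$m_r - 1L, neuron$T_ref)$r_inf
  sp <- cpp_stationary(fvg$gface, mu, (sigma + dsg)^2, fvg$dV, fvg$V_lb,
                       fvg$m_r - 1L, neuron$T_ref)$r_inf
  sm <- cpp_stationary(fvg$gface, mu, (sigma - dsg)^2, fvg$dV, fvg$V_lb,
                       fvg$m_r - 1L, neuron$T_ref)$r_inf
  dmu_r <- (rp - rm) / (2 * dmu)
  ds2_r <- (sp - sm) / (2 * dsg) / (2 * sigma)
  conj_pair <- abs(Im(sel$lam1)) > 1e-9
  q1 <- node_eigen_quantities(sel$lam1, mu, sigma, sgrid, neuron, ph$phi0)
  if (conj_pair) {
    f <- c(q1$f, Conj(q1$f)); cm <- c(q1$c_mu, Conj(q1$c_mu))
    cs <- c(q1$c_s2, Conj(q1$c_s2))
  } else {
    q2 <- node_eigen_quantities(sel$lam2, mu, sigma, sgrid, neuron, ph$phi0)
    f <- c(q1$f, q2$f); cm <- c(q1$c_mu, q2$c_mu); cs <- c(q1$c_s2, q2$c_s2)
  }
  lams <- c(sel$lam1, sel$lam2)
  list(f_cmu = Re(sum(f * cm)), f_csigma2 = Re(sum(f * cs)),
       F_mu = Re(sum(f * lams * cm)), F_sigma2 = Re(sum(f * lams * cs)),
       M = dmu_r + Re(sum(f * cm)), S = ds2_r + Re(sum(f * cs)))
}

# fill masked nodes by linear interpolation along the mu axis per column
fill_masked <- function(M) {
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    bad <- is.na(col)
    if (any(bad) && sum(!bad) >= 2)
      M[bad, j] <- stats::approx(which(!bad), col[!bad], xout = which(bad),
                                 rule = 2)$y
  }
  M
}

#' @export
print.quantity_table <- function(x, ...) {
  cat(sprintf(
    "quantity table: %d x %d grid, mu in [%g, %g], sigma in [%g, %g]\n",
    length(x$mu), length(x$sigma), min(x$mu), max(x$mu), min(x$sigma),
    max(x$sigma)))
  cat(sprintf("  arrays: %s\n", paste(names(x$arrays), collapse = ", ")))
  cat(sprintf("  neuron hash %s, masked nodes %d\n", x$hash, x$meta$masked))
  invisible(x)
}

#' Interpolate quantities from the table
#'
#' Bilinear interpolation of named arrays at one query point; complex
#' quantities are stored and interpolated component-wise.  Out-of-range
#' queries clamp to the grid boundary (with a warning unless disabled);
#' clamping can be forbidden entirely.
#'
#' @param table a \code{\link{precompute_quantities}} result
#' @param mu,sigma query point
#' @param names character vector of array names (default: all)
#' @param clamp allow boundary clamping for out-of-range queries
#' @param warn warn when clamping occurs
#' @return named list of interpolated values
#' @export
lookup <- function(table, mu, sigma, names = NULL, clamp = TRUE,
                   warn = FALSE) {
  if (is.null(names)) names <- base::names(table$arrays)
  miss <- setdiff(names, base::names(table$arrays))
  if (length(miss))
    stop("quantities not in table: ", paste(miss, collapse = ", "))
  mg <- table$mu; sg <- table$sigma
  out_of <- mu < mg[1] || mu > mg[length(mg)] ||
    sigma < sg[1] || sigma > sg[length(sg)]
  if (out_of) {
    if (!clamp) stop(sprintf("query (%g, %g) outside table bounds", mu, sigma))
    if (warn) warning(sprintf("query (%g, %g) clamped to table bounds", mu, sigma))
    mu <- min(max(mu, mg[1]), mg[length(mg)])
    sigma <- min(max(sigma, sg[1]), sg[length(sg)])
  }
  i <- findInterval(mu, mg, all.inside = TRUE)
  j <- findInterval(sigma, sg, all.inside = TRUE)
  fx <- (mu - mg[i]) / (mg[i + 1] - mg[i])
  fy <- (sigma - sg[j]) / (sg[j + 1] - sg[j])
  vals <- lapply(table$arrays[names], function(A)
    (1 - fy) * ((1 - fx) * A[i, j] + fx * A[i + 1, j]) +
      fy * ((1 - fx) * A[i, j + 1] + fx * A[i + 1, j + 1]))
  vals
}

#' Save a quantity table
#'
#' Single-file JSON container with the grid, all arrays (full precision),
#' the neuron parameters and their hash, and metadata.
#'
#' @param table a \code{\link{precompute_quantities}} result
#' @param path output file
#' @export
save_quantity_table <- function(table, path) {
  payload <- list(
    grid = list(mu = table$mu, sigma = table$sigma),
    stationary = table$arrays[intersect(names(table$arrays),
      c("r_inf", "mean_V_inf", "d_mu_r_inf", "d_sigma_r_inf",
        "d_sigma2_r_inf", "d_mu_V_inf", "d_sigma2_V_inf"))],
    spectral = table$arrays[intersect(names(table$arrays),
      c("lam1_re", "lam1_im", "lam2_re", "lam2_im", "f_cmu", "f_csigma2",
        "F_mu", "F_sigma2", "M", "S"))],
    cascade = table$arrays[intersect(names(table$arrays),
      c("tau_mu", "tau_mu_asym", "tau_sigma", "tau", "omega"))],
    meta = c(table$meta, list(hash = table$hash,
                              neuron = unclass(table$neuron))))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load a quantity table
#'
#' Restores a table written by \code{\link{save_quantity_table}} and verifies
#' the neuron-parameter hash; a mismatch between the stored hash and the
#' stored parameters indicates tampering and the load is refused.
#'
#' @param path file written by \code{\link{save_quantity_table}}
#' @return a \code{"quantity_table"}
#' @export
load_quantity_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  neuron <- do.call(neuron_params, as.list(p$meta$neuron))
  if (!identical(params_hash(neuron), p$meta$hash))
    stop("neuron-parameter hash mismatch: table metadata corrupted")
  nm <- length(p$grid$mu)
  fix <- function(x) if (is.matrix(x)) x else matrix(x, nrow = nm)
  arrays <- c(lapply(p$stationary, fix), lapply(p$spectral, fix),
              lapply(p$cascade, fix))
  arrays <- arrays[!vapply(arrays, function(a) all(is.na(a)) || length(a) == 0,
                           TRUE)]
  structure(list(mu = p$grid$mu, sigma = p$grid$sigma, arrays = arrays,
                 neuron = neuron, hash = p$meta$hash,
                 meta = p$meta[setdiff(names(p$meta), c("hash", "neuron"))]),
            class = "quantity_table")
}
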