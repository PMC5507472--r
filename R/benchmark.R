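# Benchmark harness: shared-input comparison of the reduced models against
# the aEIF network ground truth.

#' Pearson correlation between two rate series
#'
#' Sample correlation over the common grid; constant series have no defined
#' correlation and raise an error.
#'
#' @param x,y equal-length numeric vectors or \code{fp_signal}s
#' @return correlation coefficient in [-1, 1]
#' @export
pearson_rho <- function(x, y) {
  if (inherits(x, "fp_signal")) x <- x$values
  if (inherits(y, "fp_signal")) y <- y$values
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2) stop("need at least two samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(x, y)
}

#' Root-mean-square distance between two rate series
#'
#' @param x,y equal-length numeric vectors or \code{fp_signal}s
#' @return RMS distance (same units as the inputs, kHz for rates)
#' @export
rms_distance <- function(x, y) {
  if (inherits(x, "fp_signal")) x <- x$values
  if (inherits(y, "fp_signal")) y <- y$values
  if (length(x) != length(y)) stop("series lengths differ")
  sqrt(mean((x - y)^2))
}

#' Benchmark the reduced models against the aEIF network
#'
#' Reproduces the evaluation protocol: one smoothed OU realization of the
#' external mean input (and optionally of the input variance) is generated
#' and fed identically to the network simulator, the selected reduced
#' models, and optionally the Fokker-Planck solver.  After discarding an
#' initial transient, Pearson correlation and RMS distance of every model
#' rate against the network rate are reported, together with the
#' input-output reference correlation \eqn{\rho(r_N, \mu_{ext})}.
#'
#' @param neuron,coupling model parameters
#' @param mu_process an \code{\link{ou_params}} for \eqn{\mu_{ext}(t)}
#' @param sigma_ext constant external noise intensity (mV ms^-1/2), or an
#'   \code{\link{ou_params}} describing the \eqn{\sigma^2_{ext}(t)} process
#' @param table quantity table for the reduced models
#' @param models subset of \code{c("spec1","spec2","lnexp","lndos")}
#' @param include_fp also run the Fokker-Planck solver
#' @param N network size
#' @param T duration (ms)
#' @param seed integer seed (input realization and network noise)
#' @param dt_net,dt_model,dt_fp integration steps (ms)
#' @param discard initial transient to drop (ms)
#' @param bin rate bin (ms)
#' @param fp_grid optional voltage grid for the FP run
#' @return list with \code{metrics} (data.frame: model, rho, d_rms in kHz,
#'   rate mean/sd), \code{rho_input} (input-output reference), and the
#'   binned rate series
#' @export
compare_models <- function(neuron, coupling, mu_process, sigma_ext = 1.5,
                           table = NULL,
                           models = c("spec1", "spec2", "lnexp", "lndos"),
                           include_fp = FALSE, N = 10000, T = 20000,
                           seed = 1, dt_net = 0.05, dt_model = 0.01,
                           dt_fp = 0.05, discard = 1000, bin = 1,
                           fp_grid = NULL) {
  stopifnot(inherits(mu_process, "ou_params"))
  models <- match.arg(models, several.ok = TRUE)
  sig_dt <- dt_net
  mu_ext <- ou_input(mu_process, sig_dt, T, seed)
  if (inherits(sigma_ext, "ou_params")) {
    s2_ext <- ou_input(sigma_ext, sig_dt, T, seed + 1000003L,
                       floor_at = SIGMA_FLOOR^2)
  } else {
    check_sigma_floor(sigma_ext)
    s2_ext <- signal(rep(sigma_ext^2, length(mu_ext$values)), sig_dt)
  }
  net <- simulate_network(neuron, coupling, mu_ext, s2_ext, N = N,
                          dt = dt_net, T = T, seed = seed + 17L,
                          rec_dt = bin)
  keep <- signal_times(net$trace$rate) > discard
  rN <- net$trace$rate$values[keep]
  rates <- list(network = rN)
  run_one <- function(m) {
    tr <- if (m == "fp") {
      run_fp(neuron, coupling, mu_ext, s2_ext, grid = fp_grid, dt = dt_fp,
             T = T, rec_dt = bin)
    } else {
      run_rate_model(m, table, neuron, coupling, mu_ext, s2_ext,
                     dt = dt_model, T = T, rec_dt = bin)
    }
    tr$rate$values[keep]
  }
  all_models <- c(models, if (include_fp) "fp")
  metrics <- NULL
  for (m in all_models) {
    r <- tryCatch(run_one(m), error = function(e) {
      warning(sprintf("model %s failed: %s", m, conditionMessage(e)))
      NULL
    })
    rho <- if (!is.null(r) && stats::sd(r) > 0 && stats::sd(rN) > 0)
      pearson_rho(rN, r) else NA_real_
    metrics <- rbind(metrics, data.frame(
      model = m,
      rho = rho,
      d_rms = if (!is.null(r)) rms_distance(rN, r) else NA_real_,
      rate_mean = if (!is.null(r)) mean(r) else NA_real_,
      rate_sd = if (!is.null(r)) stats::sd(r) else NA_real_,
      failed = is.null(r)))
    if (!is.null(r)) rates[[m]] <- r
  }
  mu_bin <- stats::approx(signal_times(mu_ext), mu_ext$values,
                          xout = signal_times(net$trace$rate),
                          rule = 2)$y[keep]
  rho_input <- if (stats::sd(mu_bin) > 0 && stats::sd(rN) > 0)
    pearson_rho(rN, mu_bin) else NA_real_
  list(metrics = metrics, rho_input = rho_input, rates = rates,
       times = signal_times(net$trace$rate)[keep],
       network_rate_mean = mean(rN), network_rate_sd = stats::sd(rN))
}
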