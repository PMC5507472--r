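#' Simulate a network of aEIF neurons
#'
#' Euler-Maruyama ground-truth simulation of \code{N} sparsely coupled aEIF
#' neurons with delayed pulse coupling.  Each neuron receives the common
#' external moments \eqn{\mu_{ext}(t)}, \eqn{\sigma^2_{ext}(t)} through an
#' independent white-noise realization, plus voltage jumps \code{J} from its
#' \code{K} presynaptic partners after per-connection delays.  Initial
#' voltages are drawn from a Gaussian with mean \eqn{V_r - \delta V} and
#' standard deviation \eqn{\delta V/2} (\eqn{\delta V = V_T - V_r});
#' \eqn{w_i(0) = 0}.  Fully reproducible for a given seed.
#'
#' @param neuron a \code{\link{neuron_params}} object
#' @param coupling a \code{\link{coupling_params}} object
#' @param mu_ext external mean input, an \code{fp_signal} (mV/ms)
#' @param sigma_ext_sq external input variance, an \code{fp_signal} (mV^2/ms)
#' @param N number of neurons
#' @param dt integration step (ms)
#' @param T duration (ms); defaults to the signal span
#' @param seed integer seed
#' @param rec_dt rate bin and trace recording interval (ms)
#' @param want_raster also return the spike raster
#' @return list with \code{trace} (a \code{"population_trace"}: bin rate
#'   \code{r_N} in kHz, mean voltage of non-refractory neurons, mean
#'   adaptation current), \code{total_spikes}, and optionally \code{raster}
#'   (data.frame \code{neuron}, \code{time})
#' @export
simulate_network <- function(neuron, coupling, mu_ext, sigma_ext_sq, N,
                             dt = 0.05, T = NULL, seed = 1, rec_dt = 1,
                             want_raster = FALSE) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(coupling, "coupling_params"), N >= 1)
  if (coupling$K >= N && coupling$K > 0)
    stop("in-degree K must be smaller than N")
  if (is.null(T)) T <- (length(mu_ext$values) - 1) * mu_ext$dt
  rec_every <- max(1L, round(rec_dt / dt))
  n_steps <- (floor(T / dt) %/% rec_every) * rec_every
  tt <- (0:(n_steps - 1)) * dt
  mu <- stats::approx(signal_times(mu_ext), mu_ext$values, xout = tt,
                      rule = 2)$y
  s2 <- stats::approx(signal_times(sigma_ext_sq), sigma_ext_sq$values,
                      xout = tt, rule = 2)$y
  if (any(s2 < 0)) stop("external input variance must be nonnegative")
  dv0 <- neuron$V_T - neuron$V_r
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  V0 <- stats::rnorm(N, neuron$V_r - dv0, dv0 / 2)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  V0 <- pmin(V0, neuron$V_s - 1e-6)
  dk <- switch(coupling$delay_kind, none = 0L, exponential = 1L,
               identical = 2L)
  res <- cpp_simulate_network(N, n_steps, dt, mu, sqrt(s2), V0,
                              neuron$C, neuron$g_L, neuron$E_L,
                              neuron$Delta_T, neuron$V_T, neuron$V_s,
                              neuron$V_r, neuron$T_ref, neuron$a, neuron$b,
                              neuron$tau_w, neuron$E_w,
                              coupling$K, coupling$J, dk, coupling$tau_d,
                              coupling$d, seed + 1, rec_every, want_raster)
  rec <- rec_every * dt
  trace <- structure(list(
    rate = signal(res$count_bin / (N * rec), rec, rec / 2, "kHz"),
    mean_V = signal(res$mean_V, rec, rec, "mV"),
    mean_w = signal(res$mean_w, rec, rec, "pA"),
    model = "network"), class = "population_trace")
  out <- list(trace = trace, total_spikes = res$total_spikes, N = N, T = T)
  if (want_raster)
    out$raster <- data.frame(neuron = res$spike_id, time = res$spike_time)
  out
}

#' Bin a spike raster into a population rate
#'
#' \eqn{r_N(t_k)} is the spike count in \eqn{[t_k, t_k + \Delta T)} divided
#' by \eqn{N \Delta T} (kHz).  An empty raster yields an all-zero signal.
#'
#' @param raster data.frame with columns \code{neuron}, \code{time} (ms)
#' @param N population size
#' @param bin bin width \eqn{\Delta T} (ms)
#' @param T total duration (ms); defaults to the last spike time rounded up
#' @return an \code{fp_signal} (kHz)
#' @export
bin_rate <- function(raster, N, bin = 1, T = NULL) {
  stopifnot(bin > 0, N >= 1)
  if (is.null(T))
    T <- if (nrow(raster)) ceiling(max(raster$time) / bin) * bin else bin * 2
  nb <- max(2, ceiling(T / bin))
  counts <- tabulate(pmin(nb, floor(raster$time / bin) + 1L), nbins = nb)
  signal(counts / (N * bin), bin, bin / 2, "kHz")
}

#' Export a spike raster as TSV
#'
#' Two-column tab-separated file (\code{neuron_id}, \code{time_ms}), sorted
#' by time.
#' @param raster data.frame with columns \code{neuron}, \code{time}
#' @param path output file
#' @export
write_raster_tsv <- function(raster, path) {
  r <- raster[order(raster$time), c("neuron", "time")]
  names(r) <- c("neuron_id", "time_ms")
  utils::write.table(r, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
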