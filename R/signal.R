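#' Uniformly sampled time series
#'
#' Lightweight carrier for all time series handled by the package (external
#' input moments, spike rates, adaptation traces).
#'
#' @param values numeric vector of samples
#' @param dt sample spacing (ms)
#' @param t0 time of the first sample (ms)
#' @param units payload unit label (informational)
#' @return an object of class \code{"fp_signal"}
#' @export
signal <- function(values, dt, t0 = 0, units = "") {
  stopifnot(dt > 0, length(values) >= 2)
  structure(list(t0 = t0, dt = dt, values = as.numeric(values),
                 units = units), class = "fp_signal")
}

#' @export
print.fp_signal <- function(x, ...) {
  cat(sprintf("signal: %d samples, dt = %g ms, t in [%g, %g] ms%s\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt,
              if (nzchar(x$units)) paste0(", units ", x$units) else ""))
  invisible(x)
}

#' Sample times of a signal
#' @param x an \code{fp_signal}
#' @return numeric vector of times (ms)
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$values) - 1) * x$dt

#' Write a signal to CSV
#'
#' Two columns \code{t} (ms) and \code{value}; the unit label is recorded in
#' a comment header line.
#' @param x an \code{fp_signal}
#' @param path output file
#' @export
write_signal_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_ms,value  units: %s", x$units), con)
  utils::write.table(data.frame(t = signal_times(x), value = x$values),
                     con, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Ornstein-Uhlenbeck process realization
#'
#' Generates a stationary OU sample path with the exact discretization
#' \deqn{x_{n+1} = \bar{x} + (x_n - \bar{x}) e^{-\Delta t/\tau}
#'   + \vartheta \sqrt{1 - e^{-2\Delta t/\tau}} \; z_n,}
#' initialized from the stationary Normal(\code{mean}, \code{theta}^2)
#' distribution, so stationarity holds exactly at any step size (no
#' Euler-Maruyama discretization bias in the benchmark inputs).
#'
#' @param params an \code{\link{ou_params}} object
#' @param dt sample spacing (ms); must resolve the correlation time
#' @param T duration (ms)
#' @param seed integer seed; equal seeds give bit-identical series
#' @return an \code{fp_signal} of length \code{floor(T/dt) + 1}
#' @export
ou_process <- function(params, dt, T, seed) {
  stopifnot(inherits(params, "ou_params"))
  if (!(dt > 0) || !(T > 0)) stop("dt and T must be positive")
  if (dt >= params$tau_ou / 2)
    stop("dt must be smaller than tau_ou/2 to resolve the process")
  n <- floor(T / dt) + 1L
  if (params$theta == 0)
    return(signal(rep(params$mean, n), dt))
  rho <- exp(-dt / params$tau_ou)
  s <- params$theta * sqrt(1 - rho^2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  z <- stats::rnorm(n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  x <- numeric(n)
  x[1] <- params$mean + params$theta * z[1]
  innov <- s * z[-1]
  # AR(1) recursion on the centered series
  x[-1] <- stats::filter(innov, rho, method = "recursive",
                         init = x[1] - params$mean)
  x[-1] <- x[-1] + params$mean
  signal(x, dt)
}

#' Gaussian kernel smoothing of a signal
#'
#' Convolution with a normalized Gaussian kernel of standard deviation
#' \code{sigma_t}, truncated at four standard deviations, with edge
#' replication at the boundaries.  \code{sigma_t = 0} returns the input
#' unchanged.  The operation is linear and preserves affine trends in the
#' interior.
#'
#' @param x an \code{fp_signal}
#' @param sigma_t kernel standard deviation (ms)
#' @return smoothed \code{fp_signal}
#' @export
gaussian_smooth <- function(x, sigma_t) {
  stopifnot(inherits(x, "fp_signal"), sigma_t >= 0)
  if (sigma_t == 0) return(x)
  hw <- max(1L, ceiling(4 * sigma_t / x$dt))
  k <- stats::dnorm(seq(-hw, hw) * x$dt, sd = sigma_t)
  k <- k / sum(k)
  v <- x$values
  padded <- c(rep(v[1], hw), v, rep(v[length(v)], hw))
  sm <- stats::filter(padded, k, sides = 2)
  out <- as.numeric(sm[(hw + 1):(hw + length(v))])
  signal(out, x$dt, x$t0, x$units)
}

#' Generate a smoothed OU input signal
#'
#' Convenience wrapper: OU realization followed by Gaussian smoothing with
#' the width stored in the parameters.  For a variance process
#' (\code{floor_at} set) rare negative excursions are clamped at the floor
#' with a warning; parametrizations for which negative excursions are not
#' rare should be rejected by the caller.
#'
#' @param params an \code{\link{ou_params}} object
#' @param dt sample spacing (ms)
#' @param T duration (ms)
#' @param seed integer seed
#' @param floor_at optional lower clamp (used for sigma^2 processes)
#' @return an \code{fp_signal}
#' @export
ou_input <- function(params, dt, T, seed, floor_at = NULL) {
  x <- ou_process(params, dt, T, seed)
  x <- gaussian_smooth(x, params$sigma_t)
  if (!is.null(floor_at)) {
    nneg <- sum(x$values < floor_at)
    if (nneg > 0) {
      if (nneg > 0.01 * length(x$values))
        stop("more than 1% of the variance process falls below the floor; choose a larger mean or smaller theta")
      warning(sprintf("clamped %d variance samples at the floor %g", nneg,
                      floor_at))
      x$values[x$values < floor_at] <- floor_at
    }
  }
  x
}

#' Overall synaptic input moments
#'
#' Combines the external moments with the recurrent contribution of the
#' delayed population rate:
#' \deqn{\mu_{syn} = \mu_{ext} + J K r_d, \qquad
#'   \sigma^2_{syn} = \sigma^2_{ext} + J^2 K r_d.}
#' The variance contribution is positive for any sign of \code{J}.
#'
#' @param mu_ext external mean input (mV/ms)
#' @param sigma_ext_sq external input variance (mV^2/ms)
#' @param r_d delayed population rate (kHz), nonnegative
#' @param coupling a \code{\link{coupling_params}} object
#' @return list with components \code{mu_syn} and \code{sigma_syn_sq}
#' @export
synaptic_moments <- function(mu_ext, sigma_ext_sq, r_d, coupling) {
  stopifnot(inherits(coupling, "coupling_params"))
  if (any(r_d < 0)) stop("delayed rate must be nonnegative")
  if (any(sigma_ext_sq <= 0)) stop("external input variance must be positive")
  list(mu_syn = mu_ext + coupling$J * coupling$K * r_d,
       sigma_syn_sq = sigma_ext_sq + coupling$J^2 * coupling$K * r_d)
}
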