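#' Time-varying stimulus description
#'
#' The sensory input `mu_hat(t) = mu + zeta(t)`, where `zeta(t)` is
#' zero-mean Gaussian noise low-pass filtered with a digital
#' Butterworth filter and rescaled to standard deviation `sigma_c`.
#' The same realization of `zeta(t)` drives every neuron in a run
#' (it is common, sensory noise), unlike the private intrinsic white
#' noise of each cell.
#'
#' @param mu Constant bias component (dimensionless).
#' @param sigma_c Standard deviation of the fluctuation (bias units).
#' @param cutoff_hz Filter cutoff frequency (Hz).
#' @param order Butterworth filter order.
#' @param seed Integer seed for the white-noise draw.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(mu = 0, sigma_c = 0.3, cutoff_hz = 100,
                          order = 4L, seed = 1L) {
  if (sigma_c < 0) stop("sigma_c must be non-negative")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  if (order < 1) stop("order must be >= 1")
  structure(list(mu = mu, sigma_c = sigma_c, cutoff_hz = cutoff_hz,
                 order = as.integer(order), seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Generate the low-pass-filtered stimulus fluctuation
#'
#' Draws a Gaussian white sequence, passes it causally (single forward
#' pass) through a low-pass Butterworth filter at `cutoff_hz`, removes
#' the mean and rescales to standard deviation `sigma_c`. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [stimulus_spec()].
#' @param n_steps Number of samples.
#' @param dt Sample step (ms); the cutoff must lie below the Nyquist
#'   frequency `500/dt` Hz.
#' @return Numeric vector of length `n_steps` (the fluctuation
#'   `zeta(t)`, bias units).
#' @examples
#' z <- generate_filtered_noise(stimulus_spec(sigma_c = 0.3), 2000, dt = 0.5)
#' sd(z)
#' @export
generate_filtered_noise <- function(spec, n_steps, dt) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$sigma_c == 0) return(numeric(n_steps))
  nyquist <- 500 / dt  # Hz; fs = 1000/dt
  if (spec$cutoff_hz >= nyquist)
    stop("cutoff_hz must be below the Nyquist frequency ", nyquist, " Hz")
  white <- local({
    set.seed(spec$seed)
    rnorm(n_steps)
  })
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyquist, type = "low")
  z <- as.numeric(signal::filter(bf, white))
  z <- z - mean(z)
  z * spec$sigma_c / sd(z)
}
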