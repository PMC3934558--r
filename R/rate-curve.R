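#' Tabulated f-I curve
#'
#' A `rate_curve` is a data frame with columns `x` (bias `mu`, or
#' stimulus amplitude in mV/cm for the ELL module), `rate` (ms^-1),
#' `stderr` (per-point standard error, 0 for analytic curves) and
#' `source` (`"analytic"` or `"simulated"`). The refractory ceiling
#' `1/tau_r` of the generating neuron is carried as an attribute so
#' that gain fits can select relative-rate windows.
#'
#' @param x Strictly increasing input grid.
#' @param rate Firing rates (ms^-1).
#' @param stderr Standard errors (ms^-1).
#' @param source `"analytic"` or `"simulated"`.
#' @param tau_r Refractory period (ms) of the generating neuron.
#' @return An object of classes `rate_curve` and `data.frame`.
#' @export
rate_curve <- function(x, rate, stderr = rep(0, length(x)),
                       source = c("analytic", "simulated"), tau_r = 1) {
  source <- match.arg(source)
  if (length(x) > 1L && any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (length(rate) != length(x) || length(stderr) != length(x))
    stop("x, rate and stderr must have equal lengths")
  if (any(rate < -1e-12)) stop("rates must be non-negative")
  structure(data.frame(x = x, rate = rate, stderr = stderr,
                       source = source, stringsAsFactors = FALSE),
            tau_r = tau_r,
            class = c("rate_curve", "data.frame"))
}

#' Write a rate curve to CSV (rates in Hz)
#'
#' Serializes with header `x,rate_hz,stderr_hz,source`; internal ms^-1
#' rates are converted to Hz (x 1000).
#'
#' @param curve A [rate_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rate_curve"))
  out <- data.frame(x = curve$x,
                    rate_hz = curve$rate * 1000,
                    stderr_hz = curve$stderr * 1000,
                    source = curve$source)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analytic f-I curve of the target cell on a bias grid
#'
#' @param p_s,p_d [neuron_params()] for target and drive populations.
#' @param ff [feedforward_params()].
#' @param mu_grid Increasing bias grid.
#' @return A [rate_curve()] with `source = "analytic"`.
#' @export
fi_curve_analytic <- function(p_s, p_d, ff, mu_grid) {
  rate_curve(mu_grid, sp_rate(p_s, p_d, ff, mu_grid),
             source = "analytic", tau_r = p_s$tau_r)
}
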