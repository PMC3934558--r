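#' Discretized synaptic kernel
#'
#' Builds the synaptic filter on the integration grid. The delayed
#' alpha kernel `s(t) = ((t - tau_d)/tau_s^2) exp(-(t - tau_d)/tau_s)`
#' for `t > tau_d` is truncated at `tau_d + 20 tau_s` and renormalized
#' so that `sum(weights) * dt = 1`; the delta kernel puts mass `1/dt`
#' in the bin nearest `tau_d`. Weights are in ms^-1 per bin.
#'
#' @param kind `"delayed_alpha"` or `"delta"`.
#' @param tau_s Synaptic time scale (ms; alpha kernel only).
#' @param tau_d Transmission delay (ms).
#' @param dt Grid step (ms); must satisfy `dt <= tau_s / 10` for the
#'   alpha kernel.
#' @return An object of class `synaptic_kernel` with fields `kind`,
#'   `tau_s`, `tau_d`, `dt` and `weights`.
#' @examples
#' k <- build_kernel("delayed_alpha", tau_s = 5, tau_d = 10, dt = 0.1)
#' sum(k$weights) * k$dt  # 1
#' @export
build_kernel <- function(kind = c("delayed_alpha", "delta"),
                         tau_s = 5, tau_d = 10, dt = 0.05) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("dt must be positive")
  if (tau_d < 0) stop("tau_d must be non-negative")
  if (kind == "delayed_alpha") {
    if (dt > tau_s / 10)
      stop("dt too coarse for the delayed_alpha kernel; need dt <= tau_s/10")
    t_max <- tau_d + 20 * tau_s
    tt <- seq(0, t_max, by = dt)
    w <- ifelse(tt > tau_d,
                (tt - tau_d) / tau_s^2 * exp(-(tt - tau_d) / tau_s), 0)
    w <- w / (sum(w) * dt)  # unit mass on the grid
  } else {
    bin <- as.integer(round(tau_d / dt))
    w <- numeric(bin + 1L)
    w[bin + 1L] <- 1 / dt
  }
  structure(list(kind = kind, tau_s = tau_s, tau_d = tau_d, dt = dt,
                 weights = w),
            class = "synaptic_kernel")
}
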