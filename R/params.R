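#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the constants of one LIF population. Membrane potential is
#' measured in resting-to-threshold units (`V_r = 0`, `V_th = 1` by
#' default), time in milliseconds, and firing rates internally in
#' ms^-1. `sigma` is the intrinsic white-noise intensity in the
#' convention where the stationary subthreshold membrane variance is
#' `sigma^2 / 2`; `mu` is the constant sensory bias.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_r Absolute refractory period (ms).
#' @param v_th Firing threshold (dimensionless).
#' @param v_r Reset potential (dimensionless).
#' @param sigma Intrinsic noise intensity (dimensionless, >= 0).
#' @param mu Constant sensory bias (dimensionless).
#'
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params(sigma = 1)
#' @export
neuron_params <- function(tau_m = 10, tau_r = 1, v_th = 1, v_r = 0,
                          sigma = 0, mu = 0) {
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L,
            is.numeric(tau_r), length(tau_r) == 1L,
            is.numeric(v_th), length(v_th) == 1L,
            is.numeric(v_r), length(v_r) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(mu), length(mu) == 1L)
  if (tau_m <= 0) stop("tau_m must be positive")
  if (tau_r < 0) stop("tau_r must be non-negative")
  if (v_th <= v_r) stop("v_th must exceed v_r")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(tau_m = tau_m, tau_r = tau_r, v_th = v_th, v_r = v_r,
                 sigma = sigma, mu = mu),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "LIF neuron: tau_m=%g ms, tau_r=%g ms, V_th=%g, V_r=%g, sigma=%g, mu=%g\n",
    x$tau_m, x$tau_r, x$v_th, x$v_r, x$sigma, x$mu))
  invisible(x)
}

#' Feedforward-pathway parameters
#'
#' Describes the inhibitory feedforward ("open-loop feedback") pathway
#' from the drive (DP) population onto the target (SP) cell: overall
#' strength `G` (net inhibitory pathways have `G < 0`), population size
#' `N`, and the synaptic filter. The delayed alpha kernel
#' `s(t) = ((t - tau_d)/tau_s^2) exp(-(t - tau_d)/tau_s)` for
#' `t > tau_d` integrates to one; the delta kernel is a pure
#' transmission delay.
#'
#' @param G Feedforward strength (dimensionless; negative = inhibitory).
#' @param N Size of the drive population.
#' @param kernel Synaptic filter: `"delayed_alpha"` or `"delta"`.
#' @param tau_s Synaptic time scale (ms; alpha kernel only).
#' @param tau_d Transmission delay (ms).
#'
#' @return An object of class `feedforward_params`.
#' @examples
#' feedforward_params(G = -1)
#' @export
feedforward_params <- function(G = 0, N = 500,
                               kernel = c("delayed_alpha", "delta"),
                               tau_s = 5, tau_d = 10) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(G), length(G) == 1L, is.numeric(N), length(N) == 1L)
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (kernel == "delayed_alpha" && tau_s <= 0)
    stop("tau_s must be positive for the delayed_alpha kernel")
  if (tau_d < 0) stop("tau_d must be non-negative")
  structure(list(G = G, N = as.integer(N), kernel = kernel,
                 tau_s = tau_s, tau_d = tau_d),
            class = "feedforward_params")
}

#' @export
print.feedforward_params <- function(x, ...) {
  cat(sprintf("Feedforward pathway: G=%g, N=%d, kernel=%s, tau_s=%g ms, tau_d=%g ms\n",
              x$G, x$N, x$kernel, x$tau_s, x$tau_d))
  invisible(x)
}

#' Simulation configuration
#'
#' @param T_total Total simulated time (ms).
#' @param T_transient Warm-up discarded from rate estimates (ms).
#' @param dt Integration step (ms).
#' @param seed Integer seed; all randomness in a run derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(T_total = 20000, T_transient = 500, dt = 0.05,
                       seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (T_transient < 0 || T_transient >= T_total)
    stop("need 0 <= T_transient < T_total")
  structure(list(T_total = T_total, T_transient = T_transient,
                 dt = dt, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-point seed derivation: mixes the base seed with the
# point index so that grid reorderings do not change any point's stream.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 2654435761 + as.double(i) * 40503) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.double(x)
}
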