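# Shared parameter bundles. Unit tests run at reduced network size and
# duration; the canonical full-scale regimes live in figure_fixtures()
# and are exercised by the acceptance tests.

default_dp <- function(sigma = 0, ...) neuron_params(sigma = sigma, ...)

small_cfg <- function(seed = 1L, T_total = 4000, dt = 0.05) {
  sim_config(T_total = T_total, T_transient = 200, dt = dt, seed = seed)
}

# moving-average smoothing used to compare trace variances on the
# membrane time scale (removes synaptic shot noise)
smooth_trace <- function(x, width_ms, dt) {
  w <- max(1L, as.integer(round(width_ms / dt)))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}
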