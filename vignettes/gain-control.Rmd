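---
title: "Feedforward inhibition as a versatile gain control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedforward inhibition as a versatile gain control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffgain)
```

## The circuit and its model

The circuit is a two-population abstraction of the electrosensory
lateral-line lobe (ELL) of weakly electric fish. A population of `N`
deep pyramidal (DP) neurons and a representative superficial pyramidal
(SP) cell both receive the sensory drive `mu`; the DP population
additionally inhibits the SP cell through a purely feedforward pathway
of strength `G <= 0` (in the fish, via the praeminentialis nucleus and
the granule-cell parallel fibers). There is no recurrence and no
feedback from SP to DP — "open-loop feedback".

Every neuron is a leaky integrate-and-fire (LIF) unit. In
resting-to-threshold units (`V_r = 0`, `V_th = 1`), a DP membrane
obeys

$$\tau_m \dot V_i = -V_i + \mu + \text{(noise)}, $$

with threshold crossing emitting a spike, reset to `V_r` and an
absolute refractory period `tau_r`. The intrinsic noise is Gaussian
and white, independent across neurons, with intensity `sigma` in the
convention where the stationary subthreshold membrane variance is
`sigma^2/2` — the convention under which the stationary rate of a
noisy cell is the Siegert integral

$$r(\mu) = \Big[\tau_r + \tau_m \int_{z_r}^{z_{th}} \sqrt{\pi}\,
  e^{z^2}\,(1+\operatorname{erf} z)\, dz\Big]^{-1},\qquad
  z_{th} = \frac{V_{th}-\mu}{\sigma},\; z_r = \frac{V_r-\mu}{\sigma}.$$

The SP cell receives, on top of `mu`, the filtered population activity

$$f(t) = \tau_m G \,(s * Y^D)(t), \qquad
  Y^D(t) = \frac1N \sum_i \sum_k \delta(t - t_{i,k}),$$

with `s` either a delayed alpha kernel
`s(t) = ((t-tau_d)/tau_s^2) e^{-(t-tau_d)/tau_s}` (unit mass) or a
pure delay `s(t) = delta(t - tau_d)`. Averaging `f` gives the
*effective bias* `mu_eff = mu + tau_m G r_D(mu)`; the SP rate is the
SP cell's own f-I curve evaluated there. All time constants are in
milliseconds and rates internally in ms^-1, so `tau_m * G * r_D` is
dimensionless and every formula above can be coded literally; CSV
output converts to Hz.

Defaults (`neuron_params()`, `feedforward_params()`): `tau_m = 10` ms,
`tau_r = 1` ms, `tau_s = 5` ms, `tau_d = 10` ms, `N = 500`.

## The three regimes and their boundaries

With `sigma = 0` the DP onset is a hard threshold and the rate rises
logarithmically; the feedforward term then delays the SP onset —
a *subtractive* shift that approaches `|G| tau_m / tau_r` at high bias
(`sp_onset_bias()` locates the shifted onset). Noise smooths the DP
onset into a near-linear segment `r_D ≈ C1 mu + C2`
(`fit_onset_linearization()`, default window: rates between 2% and 40%
of the ceiling `1/tau_r`, since "near onset" needs a concrete
window). Propagating that line through the effective bias gives the
*divisive* relation `r_S ≈ (1 + C1 tau_m G) r_D`.

For strong inhibition the effective bias stops being monotone in `mu`.
Its extrema solve `rate_gradient(mu) = 1/(tau_m |G|)`; because the
rate gradient is unimodal (bell-shaped in `mu`, with Gaussian decay on
the subthreshold side and slow `~1/mu^2` decay on the saturating
side), solutions come in pairs — a maximum then a minimum — and exist
iff the peak gradient `gamma` exceeds `1/(tau_m |G|)`. That identity,
`|G|_c = 1/(tau_m gamma)`, is the critical line computed by
`critical_g()` and `phase_diagram()`; `find_extrema()` brackets the
two roots outward from the gradient peak, which is exact and stable
arbitrarily close to the line. `classify_regime()` therefore reports
`subtractive` iff `sigma == 0`, else `non_monotonic` iff extrema
exist, else `divisive`.

Two practical notes on the regime map. First, the `average_gain()` fit
window is the quasi-linear mid-range, rates between 10% and 60% of
`1/tau_r` (exposed as an argument). Second, the peak location
(`peak_position()`) behaves as expected — moving to lower bias with
stronger inhibition and with more noise — when the system is clearly
inside the non-monotonic region; within ~10% of the critical line the
noise-ordering of the peak can invert because the newborn peak sits
near the (noise-dependent) gradient maximum. Tests assert the
orderings away from the line.

## Simulation scheme

`simulate_circuit()` integrates the network with Euler–Maruyama at
`dt = 0.05` ms (default):

```
V <- V + (dt/tau_m) * (drive - V) + sigma * sqrt(dt/tau_m) * rnorm(1)
```

whose stationary subthreshold variance matches the `sigma^2/2`
convention of the rate formulas. Spikes are registered at the end of
the crossing step; during `tau_r` the membrane is clamped at `V_r` and
input is ignored. Plain Euler threshold detection misses excursions
between samples and underestimates rates by `O(sqrt(dt))` (about 4% at
`sigma = 1`, `dt = 0.05` ms); the integrator therefore applies the
standard diffusion continuity correction, moving the detection
boundary closer by `0.5826 * sigma * sqrt(dt/tau_m)`, which brings the
residual bias under ~0.5% without interpolating crossing times. A
dt-halving test bounds what remains.

Because the circuit is strictly feedforward, integration runs in two
exact passes: the DP population first (accumulating the spike-count
histogram), then `f(t)` by FFT convolution of that histogram with the
discretized kernel (`build_kernel()`: alpha kernel truncated at
`tau_d + 20 tau_s` and renormalized to unit mass; delta kernel one bin
of mass `1/dt`), then the SP cell. Initial membrane potentials are
drawn uniformly on `[V_r, V_th)`, which desynchronizes the noiseless
population (otherwise `sigma = 0` would produce pathological
population-wide spike synchrony that the mean-field rate theory does
not describe). The random number generator is a self-contained
xoshiro256++ stream with Box–Muller normals, seeded per neuron from
the run seed, so results are bit-reproducible for a given
`sim_config()$seed`; per-grid-point seeds are derived deterministically
from the base seed and the point index, independent of evaluation
order. Empirical rates carry Poisson-style standard errors
`sqrt(count)/window`.

## Numerical choices in the rate theory

The Siegert integrand `sqrt(pi) e^{z^2} (1 + erf z)` is evaluated as
`sqrt(pi) * erfcx(-z)` with a scaled complementary error function
built on the log of the normal tail, so the suprathreshold branch
never overflows; adaptive quadrature (`stats::integrate`,
`rel.tol = abs.tol = 1e-12`) is split at `z = 0` where the integrand
switches character. For `z_th > 25` the rate underflows double
precision and is reported as exactly 0; for `sigma < 1e-4` the
quadrature is ill-conditioned and the noiseless closed form — the
exact limit — is used instead. The closed-loop comparison model (a
single population inhibiting itself) is solved by damped fixed-point
iteration `nu <- 0.5 nu + 0.5 F(nu)` started from the open-loop rate,
to a residual below `1e-12` ms^-1; `F` is decreasing in `nu` for
`G < 0`, so the damped map converges in practice and the residual is
checked on every call.

## Time-varying stimuli and delays

`stimulus_spec()` describes the drive `mu + zeta(t)`, where `zeta` is
Gaussian white noise passed causally (single forward pass — the
physical choice; zero-phase filtering would be acausal) through a
fourth-order low-pass Butterworth filter at 100 Hz, then mean-removed
and rescaled so its standard deviation is exactly `sigma_c`. The same
`zeta` realization drives every DP neuron and the SP cell (it is
common sensory noise); intrinsic white noises stay private to each
cell.

With a delta synapse, `f(t)` is a delayed copy of the DP population
rate, and since the DP population does not depend on `tau_d`,
`covariance_f_zeta()` simulates it once and re-aligns `f` per delay —
the delay scan is exactly seed-consistent across delays. At zero delay
the inhibition tracks and cancels the slow stimulus fluctuations
(`cov(f, zeta)` strongly negative, effective-bias variance below the
stimulus variance); with tens of milliseconds of delay the
cancellation fails and can even amplify fluctuations, the covariance
rises toward zero (with a minor oscillatory component), and the extra
variability lifts the SP rate near onset — delay-induced
linearization. Variance comparisons are made on traces smoothed over
the membrane time scale, because the raw `f(t)` carries synaptic shot
noise (`~tau_m G/(N dt)` per spike per bin) that the membrane, but not
a raw variance, filters out. Transients of
`10 * max(tau_m, tau_d, 1/f_cutoff)` are discarded before estimating
covariances.

## The ELL amplitude-modulation model

The in-vivo experiments report SP rates against electric-field
amplitude modulations `E_AM` (mV/cm; `am_to_db()` uses the 2 mV/cm
zero-decibel reference). Electroreceptor afferents follow Boltzmann
tuning `r_aff/r_max = 1/(1+e^{-k(E-h)})`, and the pyramidal bias is
`mu(E) = mu0 + A/(1+e^{-k(E-h)})` with the lumped gain
`A = tau_m G_aff r_max` (the factors are never needed separately).
Working-point constants: `tau_m = 6` ms, `tau_r = 0.8` ms,
`sigma = 0.01`, `mu0 = -0.16`, `A = 2.31`, `k = 3` cm/mV, `h = 0`.
`predict_ell_curves()` produces three analytic curves: *lesion*
(parallel fibers removed, `G = 0`), *constant-G control*
(`G = -0.65`, adequate only at large amplitudes, where the afferents
saturate and divisiveness comes from saturation rather than from the
noise-linearization mechanism) and *sigmoid-G control*
(`G(E) = G0 + B/(1+e^{-kappa E})`, defaults `G0 = 0.75`, `B = -1.4`,
`kappa = 5`; an avowedly ad hoc form whose essential features are a
net excitatory value at rest, a sign change at small amplitude, and
saturation to -0.65). The direct praeminentialis inhibition is
absorbed into `mu0`; no separate parameter is fitted. Model rates are
absolute; experimentally-derived baseline offsets are *not* added (they
belong to the data, not the model), so comparisons with published
relative-rate plots require adding the user's own baselines.

Two consequences of these constants are worth stating. The model's
spontaneous bias `mu(0) = 0.995` lies only half a noise standard
deviation below threshold, so the lesion curve starts from a sizable
spontaneous rate (~20 Hz) rather than from silence; the "sharp onset"
that motivates `sigma = 0.01` is the concentration of the curve's rise
at small amplitudes, which the tests assert. And the sigmoid-G control
crosses the lesion curve where `G(E)` changes sign, at
`E ≈ 0.03` mV/cm with the default constants — below the default
plotting grid, which starts at 0.05 mV/cm; analyses of the crossing
evaluate the curves on a finer grid extended downward.

## Scale of the shipped checks

The test suite validates theory against simulation at the conditions
used throughout: `N = 500` DP neurons, 20 s of simulated time per bias
point, 15-point grids for the three regime fixtures
(`sigma = 0, G = -0.6`; `sigma = 1, G = -1`; `sigma = 1, G = -2`), and
`tau_m = 15` ms, `sigma = 0.1`, `sigma_c = 0.3`, `G = -0.6` for the
delay fixture; unit tests re-run the same machinery at reduced scale
(tens of neurons, a few seconds). Simulated-vs-analytic comparisons
use three standard errors with the null-rate Poisson error where
counts are very small.

## What the synthetic inputs do and do not emulate

The stimulus generator produces stationary, Gaussian,
low-pass-filtered drive — it emulates the slow envelope statistics
used in the delay analysis, not natural electrosensory scenes
(non-stationary, spatially structured, with behaviorally induced
correlations). Network heterogeneity is absent: all DP cells share
identical parameters, so finite-size fluctuations of `f(t)` scale as
`1/sqrt(N)` but cell-to-cell diversity effects (different biases or
noise levels for SP vs DP, mixed subtractive/non-monotonic regimes)
are out of scope. Passing tests therefore demonstrate the internal
consistency of theory and simulation under these idealized conditions,
not fidelity to raw in-vivo recordings; the ELL module in particular
is a forward prediction with printed constants, not a fit to data
points.

## Known limitations

* The analytic rates are stationary; time-dependent effects are
  accessible only through simulation (the covariance of `f` and
  `zeta` is estimated numerically, not in closed form).
* Euler–Maruyama with end-of-step spike registration biases rates at
  the `O(sqrt(dt))` level; the boundary correction removes most but
  not all of it, and `dt` much coarser than 0.05 ms is not advised.
* The frequency dependence of the feedforward strength (parallel
  fibers transmit only low frequencies in vivo) is not modeled; `G`
  is constant or amplitude-dependent, never frequency-dependent.
* `closed_loop_rate()` assumes a contracting damped map; at extreme
  parameters (very large `|G| sigma^{-1}`) convergence may require a
  smaller damping factor.
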