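# Forward model of in-vivo ELL pyramidal-cell f-I curves. The
# stimulus is an amplitude modulation (AM) of the fish's electric
# field; electroreceptor afferents encode it with Boltzmann tuning,
# their pooled drive sets the pyramidal bias mu(E_AM), and the
# parallel-fiber pathway contributes a feedforward strength G that is
# net excitatory at rest and net inhibitory for large AMs.

#' Amplitude modulation <-> decibel conversion
#'
#' `dB = 20 log10(E_AM / E_ref)` with the zero-decibel reference
#' `E_ref = 2` mV/cm.
#'
#' @param e_am Amplitude modulation (mV/cm, > 0).
#' @param db Level in dB.
#' @param e_ref Reference amplitude (mV/cm).
#' @return The converted quantity; the two functions are exact
#'   inverses.
#' @examples
#' am_to_db(2)    # 0
#' db_to_am(20)   # 20 mV/cm
#' @export
am_to_db <- function(e_am, e_ref = 2) {
  if (any(e_am <= 0)) stop("e_am must be positive")
  20 * log10(e_am / e_ref)
}

#' @rdname am_to_db
#' @export
db_to_am <- function(db, e_ref = 2) e_ref * 10^(db / 20)

#' Afferent population parameters
#'
#' Boltzmann tuning of the electroreceptor afferents and their lumped
#' synaptic drive. Individual `r_max` and afferent synaptic strength
#' are never needed separately; only the product
#' `A = tau_m * G_aff * r_max` enters the bias.
#'
#' @param A Lumped afferent gain (bias units).
#' @param k Boltzmann slope (cm/mV).
#' @param h Half-activation amplitude (mV/cm).
#' @param mu0 Intrinsic bias (bias units).
#' @return An object of class `afferent_params`. Defaults are the ELL
#'   working point: `mu0 = -0.16`, `A = 2.31`, `k = 3` cm/mV, `h = 0`.
#' @export
afferent_params <- function(A = 2.31, k = 3, h = 0, mu0 = -0.16) {
  if (k <= 0) stop("k must be positive")
  structure(list(A = A, k = k, h = h, mu0 = mu0), class = "afferent_params")
}

#' Normalized afferent firing rate
#'
#' Boltzmann (logistic) tuning `r_aff/r_max = 1/(1 + exp(-k (E - h)))`;
#' equals 1/2 at `E = h` and has slope `k/4` there.
#'
#' @param ap [afferent_params()].
#' @param e_am Amplitude modulation (mV/cm); vectorized.
#' @return Normalized rate in (0, 1).
#' @export
afferent_rate <- function(ap, e_am) {
  stopifnot(inherits(ap, "afferent_params"))
  1 / (1 + exp(-ap$k * (e_am - ap$h)))
}

#' Pyramidal-cell bias as a function of stimulus amplitude
#'
#' `mu(E_AM) = mu0 + A / (1 + exp(-k (E_AM - h)))`: intrinsic bias plus
#' the pooled afferent drive.
#'
#' @inheritParams afferent_rate
#' @return Bias value(s), dimensionless.
#' @examples
#' mu_of_am(afferent_params(), 0)  # -0.16 + 2.31/2
#' @export
mu_of_am <- function(ap, e_am) {
  stopifnot(inherits(ap, "afferent_params"))
  ap$mu0 + ap$A * afferent_rate(ap, e_am)
}

#' Stimulus-dependent feedforward strength parameters
#'
#' Sigmoidal `G(E_AM) = G0 + B / (1 + exp(-kappa E_AM))` with `B < 0`:
#' net excitatory at rest, saturating to the inhibitory value `G0 + B`
#' for strong stimuli. Defaults are the ELL values `G0 = 0.75`,
#' `B = -1.4`, `kappa = 5` cm/mV.
#'
#' @param G0 Offset.
#' @param B Amplitude (negative).
#' @param kappa Steepness (cm/mV).
#' @return An object of class `g_sigmoid_params`.
#' @export
g_sigmoid_params <- function(G0 = 0.75, B = -1.4, kappa = 5) {
  if (G0 + B >= 0)
    stop("G0 + B must be negative (net inhibitory at large amplitude)")
  structure(list(G0 = G0, B = B, kappa = kappa), class = "g_sigmoid_params")
}

#' Stimulus-dependent feedforward strength
#'
#' @param gp [g_sigmoid_params()].
#' @param e_am Amplitude modulation (mV/cm); vectorized.
#' @return Feedforward strength `G(E_AM)`; decreasing in `e_am` for
#'   `B < 0`, crossing zero at a small positive amplitude.
#' @examples
#' g_of_am(g_sigmoid_params(), 20)  # ~ -0.65
#' @export
g_of_am <- function(gp, e_am) {
  stopifnot(inherits(gp, "g_sigmoid_params"))
  gp$G0 + gp$B / (1 + exp(-gp$kappa * e_am))
}

#' Neuron constants of the ELL working point
#'
#' `tau_m = 6` ms, `tau_r = 0.8` ms, `sigma = 0.01`: the small noise is
#' dictated by the sharp onset of the lesion f-I curve on a linear
#' amplitude axis.
#'
#' @return A [neuron_params()] object.
#' @export
ell_neuron_params <- function() {
  neuron_params(tau_m = 6, tau_r = 0.8, v_th = 1, v_r = 0, sigma = 0.01)
}

#' Predicted ELL pyramidal f-I curves
#'
#' Analytic SP rate versus stimulus amplitude under three conventions
#' for the parallel-fiber pathway: `"lesion"` removes it (`G = 0`, the
#' cell follows its own Siegert curve at `mu(E_AM)`);
#' `"control_constG"` uses a fixed strength (default -0.65), which
#' captures large amplitudes but fails at small ones;
#' `"control_sigmoidG"` lets `G` vary with amplitude via
#' [g_of_am()]. Both populations are driven by the same afferent bias.
#'
#' @param ap [afferent_params()].
#' @param gp [g_sigmoid_params()] (sigmoid mode only).
#' @param p [neuron_params()]; defaults to [ell_neuron_params()].
#' @param mode One of `"lesion"`, `"control_constG"`,
#'   `"control_sigmoidG"`.
#' @param e_grid Increasing amplitude grid (mV/cm).
#' @param g_const Constant strength for `"control_constG"`.
#' @return A [rate_curve()] with `x = e_grid` (mV/cm), plus a `db`
#'   column.
#' @export
predict_ell_curves <- function(ap = afferent_params(),
                               gp = g_sigmoid_params(),
                               p = ell_neuron_params(),
                               mode = c("lesion", "control_constG",
                                        "control_sigmoidG"),
                               e_grid = exp(seq(log(0.05), log(20),
                                                length.out = 60)),
                               g_const = -0.65) {
  mode <- match.arg(mode)
  mu <- mu_of_am(ap, e_grid)
  r <- switch(mode,
    lesion = rate_stochastic(p, mu),
    control_constG = {
      ff <- feedforward_params(G = g_const)
      sp_rate(p, p, ff, mu)
    },
    control_sigmoidG = {
      g <- g_of_am(gp, e_grid)
      vapply(seq_along(mu), function(i) {
        ff <- feedforward_params(G = g[i])
        sp_rate(p, p, ff, mu[i])
      }, numeric(1))
    })
  out <- rate_curve(e_grid, r, source = "analytic", tau_r = p$tau_r)
  out$db <- am_to_db(e_grid)
  out
}
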