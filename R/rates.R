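# Closed-form stationary firing rates of the LIF populations: the
# noiseless rate, the Siegert (white-noise) rate, its derivative, the
# effective bias seen by the target cell, and the self-consistent
# closed-loop rate used for comparison with recurrent-feedback models.

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x),
# evaluated through the log of the normal tail so that the x >= 0 branch
# never overflows. The x < 0 branch grows like 2 exp(x^2) and is only
# used where the caller has bounded x.
erfcx <- function(x) {
  pos <- 2 * exp(x^2 + stats::pnorm(abs(x) * sqrt(2), lower.tail = FALSE,
                                    log.p = TRUE))
  ifelse(x >= 0, pos, 2 * exp(x^2) - pos)
}

# Integrand of the Siegert formula, sqrt(pi) e^{z^2} (1 + erf z),
# written as sqrt(pi) erfcx(-z) for numerical stability.
siegert_integrand <- function(z) sqrt(pi) * erfcx(-z)

# Above this reduced threshold distance the rate underflows double
# precision (e^{-z^2} with z > 25), so it is reported as exactly 0.
.z_max <- 25

# Below this sigma the quadrature is ill-conditioned and the noiseless
# limit is exact to double precision.
.sigma_min <- 1e-4

siegert_integral <- function(z_r, z_th) {
  quad <- function(lo, hi) {
    if (hi <= lo) return(0)
    res <- stats::integrate(siegert_integrand, lo, hi,
                            rel.tol = 1e-12, abs.tol = 1e-12,
                            subdivisions = 500L, stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected"))
      stop("Siegert quadrature failed: ", res$message)
    res$value
  }
  # split at z = 0 where the integrand switches from algebraic decay to
  # Gaussian growth
  if (z_r < 0 && z_th > 0) quad(z_r, 0) + quad(0, z_th)
  else quad(z_r, z_th)
}

#' Noiseless LIF firing rate
#'
#' Stationary rate of a deterministic (`sigma = 0`) LIF neuron under
#' constant bias: zero for `mu <= V_th`, else
#' `1 / (tau_r + tau_m log((V_r - mu)/(V_th - mu)))`.
#'
#' @param p A [neuron_params()] object (its `sigma` is ignored).
#' @param mu Bias value(s); vectorized.
#' @return Firing rate(s) in ms^-1.
#' @examples
#' p <- neuron_params()
#' rate_deterministic(p, 2)  # 1 / (1 + 10 log 2)
#' @export
rate_deterministic <- function(p, mu = p$mu) {
  stopifnot(inherits(p, "neuron_params"))
  r <- numeric(length(mu))
  sup <- mu > p$v_th
  if (any(sup)) {
    m <- mu[sup]
    r[sup] <- 1 / (p$tau_r + p$tau_m * log((p$v_r - m) / (p$v_th - m)))
  }
  r
}

#' Siegert firing rate of a noisy LIF neuron
#'
#' Stationary rate under constant bias and Gaussian white noise,
#' `r = [tau_r + tau_m I]^{-1}` with
#' `I = int_{z_r}^{z_th} sqrt(pi) e^{z^2} (1 + erf z) dz`,
#' `z_th = (V_th - mu)/sigma`, `z_r = (V_r - mu)/sigma`. Strictly
#' increasing in `mu` and bounded by `1/tau_r`. For `sigma < 1e-4` the
#' noiseless closed form is returned (the quadrature is ill-conditioned
#' there and the limit is exact).
#'
#' @inheritParams rate_deterministic
#' @return Firing rate(s) in ms^-1.
#' @examples
#' rate_stochastic(neuron_params(sigma = 1), 1)
#' @export
rate_stochastic <- function(p, mu = p$mu) {
  stopifnot(inherits(p, "neuron_params"))
  if (p$sigma <= 0) stop("rate_stochastic requires sigma > 0; use rate_deterministic")
  if (p$sigma < .sigma_min) return(rate_deterministic(p, mu))
  vapply(mu, function(m) {
    z_th <- (p$v_th - m) / p$sigma
    z_r <- (p$v_r - m) / p$sigma
    if (z_th > .z_max) return(0)
    1 / (p$tau_r + p$tau_m * siegert_integral(z_r, z_th))
  }, numeric(1))
}

#' Slope of the Siegert f-I curve
#'
#' Derivative of [rate_stochastic()] with respect to the bias, in the
#' closed form
#' `sqrt(pi) tau_m r^2 / sigma * (e^{z_th^2}(1+erf z_th) - e^{z_r^2}(1+erf z_r))`.
#' Always positive, and vanishing at both ends of the bias axis (the
#' slope is bell-shaped).
#'
#' @inheritParams rate_deterministic
#' @return Rate gradient(s) in ms^-1 per bias unit.
#' @export
rate_gradient <- function(p, mu = p$mu) {
  stopifnot(inherits(p, "neuron_params"))
  if (p$sigma <= 0) stop("rate_gradient requires sigma > 0")
  r <- rate_stochastic(p, mu)
  z_th <- (p$v_th - mu) / p$sigma
  z_r <- (p$v_r - mu) / p$sigma
  g <- ifelse(r == 0, 0,
              p$tau_m * r^2 / p$sigma *
                (siegert_integrand(z_th) - siegert_integrand(z_r)))
  pmax(g, 0)
}

# Rate dispatcher used wherever either branch may apply.
lif_rate <- function(p, mu) {
  if (p$sigma >= .sigma_min) rate_stochastic(p, mu) else rate_deterministic(p, mu)
}

#' Effective bias of the target cell
#'
#' Mean total drive received by the SP cell: the sensory bias plus the
#' feedforward term, `mu_eff = mu + tau_m G r_D(mu)`, with the drive
#' rate `r_D` taken from the noiseless or Siegert formula according to
#' `p_d$sigma`. For inhibitory pathways (`G <= 0`) it never exceeds
#' `mu`.
#'
#' @param p_d [neuron_params()] of the drive (DP) population.
#' @param ff [feedforward_params()].
#' @param mu Bias value(s); vectorized.
#' @return Effective bias value(s), same units as `mu`.
#' @export
effective_bias <- function(p_d, ff, mu = p_d$mu) {
  stopifnot(inherits(p_d, "neuron_params"), inherits(ff, "feedforward_params"))
  mu + p_d$tau_m * ff$G * lif_rate(p_d, mu)
}

#' Open-loop target-cell firing rate
#'
#' Stationary SP rate under feedforward drive: the DP rate sets the
#' effective bias, and the SP cell's own f-I curve (noiseless or
#' Siegert, by `p_s$sigma`) is evaluated there. With `G = 0` and
#' identical parameters this reduces, through the same code path, to
#' the DP curve.
#'
#' @param p_s [neuron_params()] of the target (SP) cell.
#' @param p_d [neuron_params()] of the drive (DP) population.
#' @param ff [feedforward_params()].
#' @param mu Bias value(s); vectorized.
#' @return Firing rate(s) in ms^-1.
#' @examples
#' p <- neuron_params(sigma = 1)
#' sp_rate(p, p, feedforward_params(G = -1), mu = 2)
#' @export
sp_rate <- function(p_s, p_d, ff, mu = p_d$mu) {
  stopifnot(inherits(p_s, "neuron_params"))
  mu_eff <- effective_bias(p_d, ff, mu)
  lif_rate(p_s, mu_eff)
}

#' Closed-loop (recurrent-feedback) firing rate
#'
#' Self-consistent rate of a single pyramidal population inhibiting
#' itself with strength `G`: the fixed point of
#' `nu = Siegert(mu + tau_m G nu)`, solved by damped iteration
#' `nu <- (1 - alpha) nu + alpha F(nu)` starting from the open-loop
#' Siegert rate. Serves as the comparison model for the open-loop
#' pathway: because here the inhibition throttles its own source, its
#' divisive effect is weaker.
#'
#' @param p [neuron_params()] with `sigma > 0`.
#' @param ff [feedforward_params()]; only `G` is used (must be <= 0).
#' @param mu Bias value(s); vectorized.
#' @param tol Convergence tolerance on the fixed-point residual (ms^-1).
#' @param alpha Damping factor in (0, 1].
#' @param max_iter Iteration cap.
#' @return Firing rate(s) in ms^-1 with `|nu - F(nu)| < tol`.
#' @export
closed_loop_rate <- function(p, ff, mu = p$mu, tol = 1e-12, alpha = 0.5,
                             max_iter = 10000L) {
  stopifnot(inherits(p, "neuron_params"), inherits(ff, "feedforward_params"))
  if (p$sigma <= 0) stop("closed_loop_rate requires sigma > 0")
  if (ff$G > 0) stop("closed_loop_rate requires G <= 0")
  Fmap <- function(nu, m) rate_stochastic(p, m + p$tau_m * ff$G * nu)
  vapply(mu, function(m) {
    nu <- rate_stochastic(p, m)
    for (i in seq_len(max_iter)) {
      f <- Fmap(nu, m)
      if (abs(f - nu) < tol) return(nu)
      nu <- (1 - alpha) * nu + alpha * f
    }
    stop("closed-loop fixed point did not converge at mu = ", m)
  }, numeric(1))
}

#' Linearize the drive f-I curve near its onset
#'
#' Noise smooths the DP onset into a nearly linear segment
#' `r_D ~ C1 mu + C2`; this fits that line by least squares. The
#' default window spans biases where the rate runs from 2% to 40% of
#' the ceiling `1/tau_r`.
#'
#' @param p_d [neuron_params()] with `sigma > 0`.
#' @param mu_range Length-2 bias interval; `NULL` selects the default
#'   window above.
#' @param n Number of fit points.
#' @return An object of class `linear_onset_fit` with elements `C1`
#'   (slope, ms^-1 per bias unit), `C2` (intercept, ms^-1),
#'   `fit_range` and `residual` (RMS, ms^-1).
#' @examples
#' fit_onset_linearization(neuron_params(sigma = 1))
#' @export
fit_onset_linearization <- function(p_d, mu_range = NULL, n = 50L) {
  stopifnot(inherits(p_d, "neuron_params"))
  if (p_d$sigma <= 0) stop("fit_onset_linearization requires sigma > 0")
  r_max <- 1 / p_d$tau_r
  if (is.null(mu_range)) {
    lo_hi <- vapply(c(0.02, 0.40), function(frac) {
      target <- frac * r_max
      f <- function(m) rate_stochastic(p_d, m) - target
      lo <- p_d$v_th - 10 * p_d$sigma - 5
      hi <- p_d$v_th + 10 * p_d$sigma + 5
      while (f(hi) < 0) hi <- hi + 5
      uniroot(f, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
    mu_range <- lo_hi
  }
  if (length(mu_range) != 2L || diff(mu_range) <= 0)
    stop("mu_range must be a non-degenerate increasing interval")
  mu <- seq(mu_range[1], mu_range[2], length.out = n)
  r <- rate_stochastic(p_d, mu)
  fit <- lm(r ~ mu)
  structure(list(C1 = unname(coef(fit)[2]), C2 = unname(coef(fit)[1]),
                 fit_range = mu_range,
                 residual = sqrt(mean(fit$residuals^2))),
            class = "linear_onset_fit")
}

#' @export
print.linear_onset_fit <- function(x, ...) {
  cat(sprintf("Onset linearization: r_D ~ %.5g * mu + %.5g (RMS %.3g) on [%.3g, %.3g]\n",
              x$C1, x$C2, x$residual, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
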