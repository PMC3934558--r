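# Gain-regime machinery. The slope of the drive f-I curve is
# bell-shaped in mu; its peak value gamma decides everything: extrema
# of the effective bias exist iff gamma > 1/(tau_m |G|), which is the
# critical line separating divisive from non-monotonic gain control.

# Bias scan range guaranteed to cover the bell of the rate gradient:
# widened until the gradient at both ends drops below gamma/100.
gamma_scan_range <- function(p_d, G = 1) {
  lo <- p_d$v_r - 5 * p_d$sigma
  hi <- p_d$v_th + 5 * p_d$sigma + 2
  g_mid <- max(rate_gradient(p_d, seq(lo, hi, length.out = 50)))
  for (i in 1:20) {
    if (rate_gradient(p_d, lo) < g_mid / 100 &&
        rate_gradient(p_d, hi) < g_mid / 100) break
    lo <- lo - 2 * p_d$sigma - 1
    hi <- hi + 2 * p_d$sigma + 1
  }
  c(lo, hi)
}

#' Maximum slope of the drive f-I curve
#'
#' The peak value `gamma` of the bell-shaped [rate_gradient()], located
#' by a coarse bracketing grid followed by golden-section refinement.
#'
#' @param p_d [neuron_params()] with `sigma > 0`.
#' @param n_grid Bracketing grid size.
#' @return Named list with `gamma` (ms^-1 per bias unit) and `mu_star`
#'   (the bias at which it is attained).
#' @examples
#' max_slope_gamma(neuron_params(sigma = 1))$gamma
#' @export
max_slope_gamma <- function(p_d, n_grid = 400L) {
  stopifnot(inherits(p_d, "neuron_params"))
  if (p_d$sigma <= 0) stop("max_slope_gamma requires sigma > 0")
  rng <- gamma_scan_range(p_d)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  g <- rate_gradient(p_d, grid)
  i <- which.max(g)
  if (i == 1L || i == n_grid)
    stop("failed to bracket the gradient maximum; widen the scan range")
  opt <- optimize(function(m) rate_gradient(p_d, m),
                  interval = grid[c(i - 1L, i + 1L)], maximum = TRUE,
                  tol = 1e-9 * max(p_d$sigma, 1))
  list(gamma = opt$objective, mu_star = opt$maximum)
}

#' Extrema of the effective bias
#'
#' Solves the extremum condition `d mu_eff / d mu = 0`, i.e.
#' `rate_gradient(mu) = -1/(tau_m G)`, by sign-change bracketing and
#' bisection. Because the gradient is bell-shaped the solution count is
#' 0 (sub-critical |G|) or 2 (super-critical): a maximum at smaller mu
#' followed by a minimum. Classification uses the sign of
#' `d mu_eff / d mu` on either side of each root.
#'
#' @param p_d [neuron_params()] with `sigma > 0`.
#' @param ff [feedforward_params()].
#' @param mu_range Optional length-2 scan interval; defaults to the
#'   gradient-bell covering range.
#' @param n_grid Bracketing grid size.
#' @return Data frame with columns `mu_star`, `kind`
#'   (`"maximum"`/`"minimum"`) and `mu_eff_value`; zero rows when no
#'   extrema exist.
#' @examples
#' find_extrema(neuron_params(sigma = 1), feedforward_params(G = -2))
#' @export
find_extrema <- function(p_d, ff, mu_range = NULL) {
  stopifnot(inherits(p_d, "neuron_params"), inherits(ff, "feedforward_params"))
  if (p_d$sigma <= 0) stop("find_extrema requires sigma > 0")
  empty <- data.frame(mu_star = numeric(0), kind = character(0),
                      mu_eff_value = numeric(0), stringsAsFactors = FALSE)
  if (ff$G >= 0) return(empty)
  level <- 1 / (p_d$tau_m * abs(ff$G))
  ms <- max_slope_gamma(p_d)
  if (ms$gamma <= level) return(empty)
  # the gradient is unimodal: one root on each side of its peak; push
  # the brackets out until the gradient has dropped below the level
  # (Gaussian decay on the left, algebraic ~1/mu^2 on the right)
  lo <- ms$mu_star - 2 * p_d$sigma - 1
  while (rate_gradient(p_d, lo) >= level) lo <- lo - 2 * p_d$sigma - 1
  hi <- ms$mu_star + 2 * p_d$sigma + 1
  while (rate_gradient(p_d, hi) >= level) hi <- ms$mu_star +
    2 * (hi - ms$mu_star)
  f <- function(m) rate_gradient(p_d, m) - level
  r1 <- uniroot(f, c(lo, ms$mu_star), tol = 1e-10)$root
  r2 <- uniroot(f, c(ms$mu_star, hi), tol = 1e-10)$root
  out <- data.frame(mu_star = c(r1, r2), kind = c("maximum", "minimum"),
                    mu_eff_value = effective_bias(p_d, ff, c(r1, r2)),
                    stringsAsFactors = FALSE)
  if (!is.null(mu_range))
    out <- out[out$mu_star >= mu_range[1] & out$mu_star <= mu_range[2], ]
  out
}

#' Critical feedforward strength
#'
#' The magnitude `|G|_c = 1/(tau_m gamma)` at which extrema of the
#' effective bias first appear: for `|G|` above it the gain control is
#' non-monotonic, below it divisive.
#'
#' @inheritParams max_slope_gamma
#' @return Critical magnitude `|G|_c` (dimensionless, > 0).
#' @export
critical_g <- function(p_d) {
  1 / (p_d$tau_m * max_slope_gamma(p_d)$gamma)
}

#' Classify the gain-control regime
#'
#' Subtractive iff the drive population is noiseless (`sigma = 0`);
#' otherwise non-monotonic iff effective-bias extrema exist
#' (`|G| > |G|_c`), else divisive.
#'
#' @inheritParams find_extrema
#' @return An object of class `regime_report`: `sigma`, `G`, `regime`,
#'   `gamma`, `g_critical`, `extrema`.
#' @examples
#' classify_regime(neuron_params(sigma = 1), feedforward_params(G = -1))
#' @export
classify_regime <- function(p_d, ff) {
  stopifnot(inherits(p_d, "neuron_params"), inherits(ff, "feedforward_params"))
  if (p_d$sigma == 0) {
    return(structure(list(sigma = 0, G = ff$G, regime = "subtractive",
                          gamma = NA_real_, g_critical = NA_real_,
                          extrema = NULL),
                     class = "regime_report"))
  }
  gam <- max_slope_gamma(p_d)$gamma
  ex <- find_extrema(p_d, ff)
  structure(list(sigma = p_d$sigma, G = ff$G,
                 regime = if (nrow(ex) > 0) "non_monotonic" else "divisive",
                 gamma = gam, g_critical = 1 / (p_d$tau_m * gam),
                 extrema = ex),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("Gain-control regime: %s (sigma=%g, G=%g)\n",
              x$regime, x$sigma, x$G))
  if (!is.null(x$gamma) && !is.na(x$gamma))
    cat(sprintf("  gamma=%.5g ms^-1/bias, |G|_c=%.5g\n", x$gamma, x$g_critical))
  if (!is.null(x$extrema) && nrow(x$extrema) > 0) {
    cat("  effective-bias extrema:\n")
    print(x$extrema)
  }
  invisible(x)
}

#' Critical line of the regime phase diagram
#'
#' Tabulates `|G|_c(sigma) = 1/(tau_m gamma(sigma))` over a noise grid:
#' the boundary between the divisive and non-monotonic regions (the
#' subtractive regime is the `sigma = 0` axis).
#'
#' @param sigma_grid Positive noise intensities.
#' @param p_template [neuron_params()] supplying all other constants.
#' @return Data frame with columns `sigma` and `g_critical`.
#' @export
phase_diagram <- function(sigma_grid, p_template = neuron_params()) {
  if (any(sigma_grid <= 0)) stop("sigma_grid must be positive")
  gc <- vapply(sigma_grid, function(s) {
    p <- p_template
    p$sigma <- s
    critical_g(p)
  }, numeric(1))
  data.frame(sigma = sigma_grid, g_critical = gc)
}

#' Average gain of an f-I curve
#'
#' Ordinary-least-squares slope over the quasi-linear mid-range of the
#' curve: the points whose rate lies between the given fractions of
#' the ceiling `1/tau_r` (default 10%-60%).
#'
#' @param curve A [rate_curve()].
#' @param fit_fraction_range Length-2 fractions of `1/tau_r` bounding
#'   the fit window.
#' @return Named vector `c(slope, slope_err)` (ms^-1 per bias unit).
#' @export
average_gain <- function(curve, fit_fraction_range = c(0.1, 0.6)) {
  stopifnot(inherits(curve, "rate_curve"))
  r_max <- 1 / attr(curve, "tau_r")
  sel <- curve$rate >= fit_fraction_range[1] * r_max &
    curve$rate <= fit_fraction_range[2] * r_max
  if (sum(sel) < 3L)
    stop("fewer than 3 curve points fall in the fit window")
  fit <- lm(rate ~ x, data = curve[sel, ])
  est <- summary(fit)$coefficients["x", c("Estimate", "Std. Error")]
  c(slope = unname(est[1]), slope_err = unname(est[2]))
}

#' Firing-onset bias of the target cell in the noiseless regime
#'
#' For `sigma = 0` the SP cell starts firing where the effective bias
#' first exceeds threshold. With inhibitory feedforward the slow
#' (logarithmic) rise of the drive rate just above its own onset pulls
#' the effective bias back below threshold, so the SP onset is shifted
#' to the right of `V_th` -- the subtractive signature. Located by
#' bisection on `mu_eff(mu) = V_th`.
#'
#' @inheritParams find_extrema
#' @param mu_max Upper search bound.
#' @return The SP onset bias (> `V_th` for `G < 0`).
#' @export
sp_onset_bias <- function(p_d, ff, mu_max = 100) {
  stopifnot(inherits(p_d, "neuron_params"), inherits(ff, "feedforward_params"))
  if (p_d$sigma != 0) stop("sp_onset_bias applies to the noiseless regime")
  if (ff$G >= 0) return(p_d$v_th)
  f <- function(m) effective_bias(p_d, ff, m) - p_d$v_th
  lo <- p_d$v_th + 1e-9
  if (f(lo) > 0) return(p_d$v_th)
  uniroot(f, c(lo, mu_max), tol = 1e-10)$root
}

#' Position of the target-cell rate peak
#'
#' In the non-monotonic regime the SP rate inherits the maximum of the
#' effective bias (the SP f-I curve is monotone in `mu_eff`), so the
#' peak sits at the maximum-kind extremum.
#'
#' @inheritParams find_extrema
#' @param p_s Target-cell [neuron_params()] (unused by the location
#'   itself; kept for interface symmetry and validation).
#' @return The bias `mu_peak` at the SP rate maximum.
#' @export
peak_position <- function(p_d, p_s, ff) {
  rep_ <- classify_regime(p_d, ff)
  if (rep_$regime != "non_monotonic")
    stop("peak_position requires the non-monotonic regime (got ",
         rep_$regime, ")")
  rep_$extrema$mu_star[rep_$extrema$kind == "maximum"][1L]
}
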