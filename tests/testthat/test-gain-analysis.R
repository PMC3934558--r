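# Gain-regime machinery: gamma, extrema, critical line, phase diagram,
# average gain and peak position.

test_that("gamma matches a brute-force scan of the gradient", {
  for (sig in c(0.5, 1, 2)) {
    p <- neuron_params(sigma = sig)
    ms <- max_slope_gamma(p)
    grid <- seq(p$v_r - 5 * sig, p$v_th + 5 * sig + 2, length.out = 10000)
    expect_equal(ms$gamma, max(rate_gradient(p, grid)), tolerance = 1e-4)
    expect_gt(ms$gamma, 0)
    # local optimality of the returned argmax
    expect_gte(rate_gradient(p, ms$mu_star) + 1e-12,
               rate_gradient(p, ms$mu_star + 0.05) - 1e-9)
    expect_gte(rate_gradient(p, ms$mu_star) + 1e-12,
               rate_gradient(p, ms$mu_star - 0.05) - 1e-9)
  }
})

test_that("extrema come in pairs (maximum first) or not at all", {
  p <- neuron_params(sigma = 1)
  ex <- find_extrema(p, feedforward_params(G = -2))
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$kind, c("maximum", "minimum"))
  expect_lt(ex$mu_star[1], ex$mu_star[2])
  # at the roots the effective-bias derivative vanishes
  for (m in ex$mu_star)
    expect_equal(1 + 10 * (-2) * rate_gradient(p, m), 0, tolerance = 1e-7)
  expect_equal(nrow(find_extrema(p, feedforward_params(G = 0))), 0L)
  # sub-critical strength: |G| at half the critical value
  gc <- critical_g(p)
  expect_equal(nrow(find_extrema(p, feedforward_params(G = -0.5 * gc))), 0L)
})

test_that("extrema count is 0 or 2 across a parameter sweep", {
  sigmas <- c(0.25, 0.5, 1, 2, 3)
  gs <- -c(0.1, 0.5, 1, 2, 4)
  for (sig in sigmas) {
    p <- neuron_params(sigma = sig)
    for (g in gs) {
      n <- nrow(find_extrema(p, feedforward_params(G = g)))
      expect_true(n %in% c(0L, 2L),
                  label = sprintf("extrema count at sigma=%g G=%g", sig, g))
    }
  }
})

test_that("critical strength separates 0-extrema from 2-extrema regions", {
  for (sig in c(0.5, 1, 2)) {
    p <- neuron_params(sigma = sig)
    gc <- critical_g(p)
    expect_gt(gc, 0)
    expect_true(is.finite(gc))
    expect_equal(nrow(find_extrema(p, feedforward_params(G = -1.05 * gc))), 2L)
    expect_equal(nrow(find_extrema(p, feedforward_params(G = -0.95 * gc))), 0L)
  }
})

test_that("regime classification follows noise and feedforward strength", {
  expect_equal(classify_regime(neuron_params(sigma = 0),
                               feedforward_params(G = -0.6))$regime,
               "subtractive")
  expect_equal(classify_regime(neuron_params(sigma = 1),
                               feedforward_params(G = -1))$regime,
               "divisive")
  expect_equal(classify_regime(neuron_params(sigma = 1),
                               feedforward_params(G = -2))$regime,
               "non_monotonic")
  # consistency with the critical line on both sides, random sigmas
  set.seed(4)
  for (sig in runif(10, 0.3, 2.5)) {
    p <- neuron_params(sigma = sig)
    gc <- critical_g(p)
    expect_equal(classify_regime(p, feedforward_params(G = -1.1 * gc))$regime,
                 "non_monotonic")
    expect_equal(classify_regime(p, feedforward_params(G = -0.9 * gc))$regime,
                 "divisive")
  }
})

test_that("phase diagram rows satisfy the critical-line identity", {
  sig <- c(0.25, 0.5, 1, 2)
  pd <- phase_diagram(sig)
  expect_equal(nrow(pd), length(sig))
  for (i in seq_along(sig)) {
    gam <- max_slope_gamma(neuron_params(sigma = sig[i]))$gamma
    expect_equal(gam * 10 * pd$g_critical[i], 1, tolerance = 1e-6)
  }
  expect_error(phase_diagram(c(0, 1)), "positive")
})

test_that("average gain is exact on a line and decreases with |G|", {
  mu <- seq(0, 10, length.out = 30)
  lin <- rate_curve(mu, pmin(0.07 * mu + 0.01, 0.99), tau_r = 1)
  g <- suppressWarnings(average_gain(lin))  # lm warns on an exact fit
  expect_equal(unname(g["slope"]), 0.07, tolerance = 1e-10)
  expect_lt(unname(g["slope_err"]), 1e-10)
  p <- neuron_params(sigma = 1)
  mu2 <- seq(-2, 6, length.out = 150)
  slopes <- vapply(c(0, -0.5, -1), function(gg) {
    average_gain(fi_curve_analytic(p, p, feedforward_params(G = gg),
                                   mu2))["slope"]
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))  # stronger inhibition, smaller gain
  expect_error(average_gain(rate_curve(1:3, c(0, 0, 0), tau_r = 1)), "window")
})

test_that("divisive regime: target curve is a near-pure rescaling of the drive curve", {
  p <- neuron_params(sigma = 1)
  mu <- seq(-2, 6, length.out = 100)
  r_d <- rate_stochastic(p, mu)
  for (g in c(-0.5, -1)) {
    r_s <- sp_rate(p, p, feedforward_params(G = g), mu)
    a <- sum(r_s * r_d) / sum(r_d^2)  # best pure-slope rescaling
    rms <- sqrt(mean((r_s - a * r_d)^2))
    expect_lt(rms, 0.10 * diff(range(r_s)))
  }
})

test_that("noiseless onset shift grows with |G| (subtractive signature)", {
  p0 <- neuron_params(sigma = 0)
  on3 <- sp_onset_bias(p0, feedforward_params(G = -0.3))
  on6 <- sp_onset_bias(p0, feedforward_params(G = -0.6))
  expect_gt(on3, p0$v_th)
  expect_gt(on6, on3)
  expect_identical(sp_onset_bias(p0, feedforward_params(G = 0)), p0$v_th)
})

test_that("rate peak sits at the effective-bias maximum and shifts as expected", {
  p1 <- neuron_params(sigma = 1)
  p2 <- neuron_params(sigma = 2)
  # brute-force argmax of the analytic SP curve over the rising-and-
  # falling stretch (up to the effective-bias minimum, beyond which the
  # curve eventually rises again) agrees with peak_position
  ff <- feedforward_params(G = -2)
  ex <- find_extrema(p2, ff)
  mu <- seq(-4, ex$mu_star[ex$kind == "minimum"], length.out = 4000)
  brute <- mu[which.max(sp_rate(p2, p2, ff, mu))]
  expect_equal(peak_position(p2, p2, ff), brute, tolerance = 0.01)
  # stronger inhibition moves the peak to lower bias
  pk1 <- vapply(c(-1.5, -2, -3), function(g)
    peak_position(p1, p1, feedforward_params(G = g)), numeric(1))
  expect_true(all(diff(pk1) < 0))
  pk2 <- vapply(c(-2, -2.5, -3), function(g)
    peak_position(p2, p2, feedforward_params(G = g)), numeric(1))
  expect_true(all(diff(pk2) < 0))
  # more noise moves the peak to lower bias at fixed G (checked away
  # from the critical line, where both noise levels are deep in the
  # non-monotonic regime)
  ff3 <- feedforward_params(G = -3)
  expect_lt(peak_position(p2, p2, ff3), peak_position(p1, p1, ff3))
  expect_error(peak_position(p1, p1, feedforward_params(G = -0.5)),
               "non-monotonic")
})
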