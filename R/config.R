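# Configuration, fixtures and scenario runner: the plumbing that ties
# the analytic, simulation, gain-analysis, delay and ELL modules to
# YAML configs, CSV/JSON outputs and the `ffgain` command-line script.

#' Named parameter fixtures for the canonical regimes
#'
#' Parameter bundles reproducing the study conditions of each
#' gain-control regime: `subtractive` (noiseless, `G` in {0, -0.3,
#' -0.6}), `divisive` (`sigma = 1`, `G` in {0, -0.5, -1}),
#' `non_monotonic` (`sigma` in {1, 2}, `G` in {-1.5, -2, -3}),
#' `delay` (`sigma = 0.1`, `sigma_c = 0.3`, `tau_m = 15` ms, delta
#' synapse, `G = -0.6`, delays {0, 10, 20} ms) and `ell` (the in-vivo
#' working point).
#'
#' @return Named list of fixture descriptions.
#' @export
figure_fixtures <- function() {
  list(
    subtractive = list(sigma = 0, G = c(0, -0.3, -0.6),
                       mu_grid = seq(-2, 6, length.out = 15)),
    divisive = list(sigma = 1, G = c(0, -0.5, -1),
                    mu_grid = seq(-2, 6, length.out = 15)),
    non_monotonic = list(sigma = c(1, 2), G = c(-1.5, -2, -3),
                         mu_grid = seq(-2, 6, length.out = 15)),
    delay = list(sigma = 0.1, sigma_c = 0.3, tau_m = 15, G = -0.6,
                 cutoff_hz = 100, tau_d = c(0, 10, 20), kernel = "delta"),
    ell = list(tau_m = 6, tau_r = 0.8, sigma = 0.01,
               mu0 = -0.16, A = 2.31, k = 3, h = 0,
               G0 = 0.75, B = -1.4, kappa = 5, g_const = -0.65)
  )
}

config_defaults <- function() {
  list(
    scenario = "fi_curve",
    dp = list(tau_m = 10, tau_r = 1, v_th = 1, v_r = 0, sigma = 0, mu = 0),
    sp = NULL,  # NULL = same as dp
    feedforward = list(G = 0, N = 500, kernel = "delayed_alpha",
                       tau_s = 5, tau_d = 10),
    stimulus = NULL,
    # note: the point-count key is "points", not "n" (YAML 1.1 parses a
    # bare n as a boolean)
    mu_grid = list(from = -2, to = 6, points = 15),
    sim = list(T_total = 20000, T_transient = 500, dt = 0.05, seed = 1),
    out_dir = "."
  )
}

validate_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file describing a scenario (`fi_curve`, `classify`,
#' `phase_diagram`, `delay_scan` or `ell`), fills omitted fields with
#' the package defaults (`tau_m = 10` ms, `tau_r = 1` ms, `tau_s = 5`
#' ms, `tau_d = 10` ms, `V_th = 1`, `V_r = 0`, `N = 500`), rejects
#' unknown keys and checks every component invariant.
#'
#' @param path Path to a YAML config file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  validate_keys(raw, names(defaults), "top level")
  for (sect in c("dp", "sp", "feedforward", "stimulus", "sim", "mu_grid")) {
    if (!is.null(raw[[sect]])) {
      allowed <- switch(sect,
        dp = , sp = c("tau_m", "tau_r", "v_th", "v_r", "sigma", "mu"),
        feedforward = c("G", "N", "kernel", "tau_s", "tau_d"),
        stimulus = c("mu", "sigma_c", "cutoff_hz", "order", "seed"),
        sim = c("T_total", "T_transient", "dt", "seed"),
        mu_grid = c("from", "to", "points"))
      validate_keys(raw[[sect]], allowed, sect)
    }
  }
  cfg <- modifyList(defaults, raw)
  cfg[vapply(cfg, is.null, logical(1))] <- NULL  # keeps save/load idempotent
  # constructing the component objects runs every invariant check
  p_d <- do.call(neuron_params, cfg$dp)
  p_s <- if (is.null(cfg$sp)) p_d else
    do.call(neuron_params, modifyList(cfg$dp, cfg$sp))
  ff <- do.call(feedforward_params, cfg$feedforward)
  stim <- if (is.null(cfg$stimulus)) NULL else
    do.call(stimulus_spec, cfg$stimulus)
  sim <- do.call(sim_config, cfg$sim)
  structure(list(scenario = cfg$scenario, p_d = p_d, p_s = p_s, ff = ff,
                 stimulus = stim,
                 mu_grid = seq(cfg$mu_grid$from, cfg$mu_grid$to,
                               length.out = cfg$mu_grid$points),
                 sim = sim, out_dir = cfg$out_dir, raw = cfg),
            class = "run_config")
}

#' Save a run configuration back to YAML
#'
#' Writes the fully-defaulted config so that a saved file reloads to an
#' identical `run_config` (round-trip identity).
#'
#' @param cfg A `run_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}

#' Run a configured scenario and write its outputs
#'
#' Dispatches on `cfg$scenario`:
#' \describe{
#'   \item{`fi_curve`}{analytic + simulated SP f-I curves and the
#'     average gain (CSV).}
#'   \item{`classify`}{regime report (JSON).}
#'   \item{`phase_diagram`}{critical line `sigma, g_critical` (CSV).}
#'   \item{`delay_scan`}{`tau_d_ms, cov_f_zeta` (CSV).}
#'   \item{`ell`}{the three predicted amplitude-response curves (CSV).}
#' }
#' A `manifest.json` recording the seed, full parameter set and package
#' version accompanies every run; outputs are byte-identical across
#' repeated runs with the same seed.
#'
#' @param cfg A `run_config`.
#' @param simulate For `fi_curve`: also run the network simulation
#'   (slow) in addition to the analytic curve.
#' @return Named character vector of the files written, invisibly.
#' @export
run_scenario <- function(cfg, simulate = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  pth <- function(f) file.path(cfg$out_dir, f)
  if (cfg$scenario == "fi_curve") {
    ana <- fi_curve_analytic(cfg$p_s, cfg$p_d, cfg$ff, cfg$mu_grid)
    write_rate_curve(ana, pth("fi_curve_analytic.csv"))
    out <- c(analytic = pth("fi_curve_analytic.csv"))
    if (simulate) {
      sim <- fi_curve_simulated(cfg$p_d, cfg$p_s, cfg$ff, cfg$mu_grid,
                                cfg$sim)
      write_rate_curve(sim, pth("fi_curve_simulated.csv"))
      out <- c(out, simulated = pth("fi_curve_simulated.csv"))
    }
    gain <- tryCatch(average_gain(ana), error = function(e) c(NA, NA))
    writeLines(sprintf("slope_ms,slope_err_ms\n%.10g,%.10g",
                       gain[1], gain[2]), pth("average_gain.csv"))
    out <- c(out, gain = pth("average_gain.csv"))
  } else if (cfg$scenario == "classify") {
    rep_ <- classify_regime(cfg$p_d, cfg$ff)
    jsonlite::write_json(
      list(sigma = rep_$sigma, G = rep_$G, regime = rep_$regime,
           gamma = rep_$gamma, g_critical = rep_$g_critical,
           extrema = rep_$extrema),
      pth("regime_report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    out <- c(report = pth("regime_report.json"))
  } else if (cfg$scenario == "phase_diagram") {
    sig <- cfg$p_d$sigma
    grid <- if (sig > 0) sig else seq(0.25, 3, length.out = 12)
    pd <- phase_diagram(grid, cfg$p_d)
    write.csv(pd, pth("phase_diagram.csv"), row.names = FALSE, quote = FALSE)
    out <- c(phase_diagram = pth("phase_diagram.csv"))
  } else if (cfg$scenario == "delay_scan") {
    stim <- if (is.null(cfg$stimulus)) stimulus_spec() else cfg$stimulus
    ffd <- cfg$ff
    ffd$kernel <- "delta"
    scan <- covariance_f_zeta(cfg$p_d, ffd, stim,
                              tau_d_grid = seq(0, 50, by = 5),
                              cfg = cfg$sim)
    write.csv(scan, pth("delay_scan.csv"), row.names = FALSE, quote = FALSE)
    out <- c(delay_scan = pth("delay_scan.csv"))
  } else if (cfg$scenario == "ell") {
    for (mode in c("lesion", "control_constG", "control_sigmoidG")) {
      curve <- predict_ell_curves(mode = mode)
      df <- data.frame(e_am_mv_per_cm = curve$x, db = curve$db,
                       rate_hz = curve$rate * 1000)
      f <- pth(paste0("ell_", mode, ".csv"))
      write.csv(df, f, row.names = FALSE, quote = FALSE)
      out <- c(out, stats::setNames(f, mode))
    }
  } else {
    stop("unknown scenario: ", cfg$scenario)
  }
  manifest <- list(scenario = cfg$scenario, seed = cfg$sim$seed,
                   parameters = cfg$raw,
                   package_version = as.character(utils::packageVersion("ffgain")))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(out, manifest = pth("manifest.json")))
}
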