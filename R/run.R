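# End-to-end orchestration: one YAML config drives power -> photon flux ->
# fit -> report. The inst/scripts/photokin-qy script is a thin wrapper
# around these functions; all logic lives here.

#' Load a run configuration
#'
#' YAML key-value config. Relative paths are resolved against the config
#' file's directory. Validated eagerly: every referenced file must exist
#' and mode-required keys must be present before any computation starts.
#'
#' @param path Config file path.
#' @param overrides Named list of keys overriding the file's values (CLI
#'   flags).
#' @return Named list (class `photokin_config`).
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (k in c("eps_A", "eps_B", "emission", "timeseries"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- resolve(cfg[[k]])
  if (!is.null(cfg$power_logs))
    cfg$power_logs <- vapply(cfg$power_logs, resolve, "")
  for (k in c("eps_A", "eps_B", "emission", "timeseries"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      .stopf("config key '%s': file not found: %s", k, cfg[[k]],
             class = "photokin_config")
  for (p in cfg$power_logs)
    if (!file.exists(p))
      .stopf("power log not found: %s", p, class = "photokin_config")
  # YAML only recognizes exponent floats with a signed exponent; coerce
  # the numeric keys so "1.7e15" works too
  num_keys <- c("excitation_nm", "volume_L", "path_irradiation_cm",
                "path_probe_cm", "k_BA", "temperature_C", "on_start",
                "on_end", "q0", "power_W", "phi_AB", "phi_BA",
                "total_conc_M", "initial_absorbance", "duration_s",
                "interval_s", "settle_time_s", "loss_fraction",
                "baseline_degree", "power_bound_multiple", "dead_time_s",
                "observation_nm", "seed")
  for (k in intersect(num_keys, names(cfg)))
    cfg[[k]] <- as.numeric(cfg[[k]])
  mode <- cfg$mode %||% "monochromatic"
  if (!mode %in% c("monochromatic", "integrated-emission"))
    .stopf("mode must be 'monochromatic' or 'integrated-emission'",
           class = "photokin_config")
  if (mode == "monochromatic" && is.null(cfg$excitation_nm))
    .stopf("monochromatic mode requires 'excitation_nm'",
           class = "photokin_config")
  if (mode == "integrated-emission" && is.null(cfg$emission))
    .stopf("integrated-emission mode requires an 'emission' spectrum file",
           class = "photokin_config")
  cfg$mode <- mode
  structure(cfg, class = "photokin_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_geometry <- function(cfg) {
  experiment_geometry(cfg$path_irradiation_cm %||% 1,
                      cfg$path_probe_cm %||% 1,
                      cfg$volume_L %||% 3e-3,
                      cfg$temperature_C %||% 20)
}

#' Power workflow: logs to pooled sample-position power
#'
#' For every log: baseline subtraction on LED-off samples, plateau
#' averaging; bare/through pairs (keys `power_logs_bare` /
#' `power_logs_through`) are combined by the transmission-loss correction;
#' a plain `power_logs` list skips the correction (flagged on the result).
#' Replicates are pooled by inverse-variance weighting.
#'
#' @param cfg A `photokin_config` (or plain named list with the same keys:
#'   `power_logs`, optional `on_start`/`on_end`, `baseline_degree`,
#'   `settle_time_s`, `loss_fraction`).
#' @param out Optional path for the key-value power report.
#' @return The pooled `photokin_power_result`.
#' @export
run_power <- function(cfg, out = NULL) {
  one <- function(path) {
    on <- if (!is.null(cfg$on_start)) c(cfg$on_start, cfg$on_end) else NULL
    tr <- read_power_trace(path, on)
    if (is.null(tr$on_interval)) tr <- detect_on_interval(tr)
    tr <- subtract_baseline(tr, cfg$baseline_degree %||% 1L)
    average_on_power(tr, cfg$settle_time_s %||% 5)
  }
  if (!is.null(cfg$power_logs_bare)) {
    if (length(cfg$power_logs_bare) != length(cfg$power_logs_through))
      .stopf("power_logs_bare and power_logs_through must pair up",
             class = "photokin_config")
    results <- Map(function(b, th)
      correct_transmission_loss(one(b), one(th),
                                cfg$loss_fraction %||% 0.5),
      cfg$power_logs_bare, cfg$power_logs_through)
  } else {
    if (is.null(cfg$power_logs) || !length(cfg$power_logs))
      .stopf("no power logs in config", class = "photokin_config")
    results <- lapply(cfg$power_logs, one)
  }
  pooled <- weighted_mean_power(results)
  if (!is.null(out)) write_power_result(pooled, out)
  pooled
}

.cfg_source <- function(cfg, power) {
  if (cfg$mode == "monochromatic")
    photon_flux(power, wavelength = cfg$excitation_nm)
  else
    photon_flux(power, emission = read_spectrum(cfg$emission),
                emission_basis = cfg$emission_basis %||% "power")
}

#' Fit workflow: data files to quantum yields with total uncertainty
#'
#' Loads the absorptivity spectra and the absorbance time series, builds
#' the photon flux from the pooled power, fits the yield pair at the
#' irradiation wavelength (or jointly over `observation_nm`), propagates
#' the power limits, and writes a key-value report.
#'
#' @param cfg A `photokin_config`.
#' @param power Optional precomputed `photokin_power_result`; by default
#'   [run_power()] is invoked on the config's logs.
#' @param out Optional report path (key-value text).
#' @return The completed `photokin_qyfit`.
#' @export
run_fit <- function(cfg, power = NULL, out = NULL) {
  if (is.null(power)) power <- run_power(cfg)
  system <- photoswitch_system(read_spectrum(cfg$eps_A),
                               read_spectrum(cfg$eps_B),
                               cfg$k_BA %||% 0)
  geometry <- .cfg_geometry(cfg)
  source <- .cfg_source(cfg, power)
  sts <- read_time_series(cfg$timeseries)
  initial <- initial_state_from_absorbance(sts, system, geometry)
  obs_wl <- cfg$observation_nm %||%
    (if (cfg$mode == "monochromatic") cfg$excitation_nm
     else source$f$wavelength[which.max(source$f$value)])
  A <- vapply(obs_wl, function(w) absorbance_trace(sts, w)$absorbance,
              numeric(length(sts$times)))
  fit <- fit_quantum_yields(
    sts$times, A, system, source, geometry, initial,
    obs_wavelengths = obs_wl,
    init = unlist(cfg$init %||% c(0.3, 0.3)),
    thermal = cfg$thermal %||% TRUE,
    fit_initial_fraction = isTRUE(cfg$fit_initial_fraction),
    dead_time = cfg$dead_time_s %||% 0)
  fit <- propagate_power_uncertainty(fit, power,
                                     multiple = cfg$power_bound_multiple %||% 1)
  if (!is.null(out)) write_fit_report(fit, out)
  fit
}

#' Simulation workflow: scenario config to a model time series file
#'
#' Forward-simulates the configured system at given yields (`phi_AB`,
#' `phi_BA` keys) and writes the wide-format absorbance time series,
#' round-trippable through [read_time_series()].
#'
#' @param cfg A `photokin_config` with additionally `phi_AB`, `phi_BA`,
#'   `q0` or `power_W`, `total_conc_M` (or `initial_absorbance`),
#'   optional `duration_s`, `interval_s`.
#' @param out Output file path for the time series.
#' @return The simulated `photokin_sts`, invisibly.
#' @export
run_simulate <- function(cfg, out) {
  system <- photoswitch_system(read_spectrum(cfg$eps_A),
                               read_spectrum(cfg$eps_B),
                               cfg$k_BA %||% 0)
  geometry <- .cfg_geometry(cfg)
  power <- if (!is.null(cfg$q0)) NULL else
    power_result_new(cfg$power_W %||%
                       .stopf("need 'q0' or 'power_W'",
                              class = "photokin_config"), 0)
  source <- if (!is.null(cfg$q0)) {
    if (cfg$mode == "monochromatic")
      monochromatic_source(cfg$q0, cfg$excitation_nm)
    else polychromatic_source(cfg$q0, read_spectrum(cfg$emission))
  } else .cfg_source(cfg, power)
  grid <- common_grid(system$eps_A, system$eps_B)[[1L]]$wavelength
  conc <- cfg$total_conc_M %||% {
    a0 <- cfg$initial_absorbance %||%
      .stopf("need 'total_conc_M' or 'initial_absorbance'",
             class = "photokin_config")
    wl <- cfg$excitation_nm
    a0 / (interpolate_spectrum(system$eps_A, wl) * geometry$path_probe)
  }
  times <- irradiation_schedule(cfg$duration_s %||% 3600,
                                cfg$interval_s %||% 30)
  sts <- simulate_spectra(system,
                          quantum_yields(cfg$phi_AB, cfg$phi_BA),
                          source, geometry,
                          kinetic_state(conc, 0), times, grid)
  write_time_series(sts, out)
  invisible(sts)
}

#' Fixture-generation workflow
#'
#' Thin wrapper over [generate_fixture_set()] taking its options from a
#' named list (CLI flags).
#'
#' @param dir Output directory.
#' @param opts Named list of [generate_fixture_set()] arguments.
#' @return The directory path, invisibly.
#' @export
run_generate <- function(dir, opts = list()) {
  do.call(generate_fixture_set, c(list(dir = dir), opts))
}
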