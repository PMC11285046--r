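# Synthetic fixtures with known ground truth: an azobenzene-like toy
# switch (Gaussian absorption bands), Gaussian LED profiles, noisy
# absorbance time series from the forward model, and drifting thermopile
# power logs. Everything is a pure function of (spec, seed).

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.gauss_bands <- function(grid, bands) {
  v <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    v <- v + bands$height[i] *
      exp(-4 * log(2) * (grid - bands$center[i])^2 / bands$fwhm[i]^2)
  v
}

#' Band table for the azobenzene-like default toy switch
#'
#' Isomer A (stable, trans-like): strong pi->pi* band near 320 nm, very
#' weak n->pi* band near 440 nm. Isomer B (metastable, cis-like): bands
#' near 240 and 280 nm and a somewhat stronger n->pi* band near 440 nm.
#' Heights are in M^-1 cm^-1, centers and FWHM in nm.
#'
#' @return List with data frames `A` and `B` (columns `center`, `fwhm`,
#'   `height`).
#' @export
azobenzene_like_bands <- function() {
  list(
    A = data.frame(center = c(320, 228, 440),
                   fwhm   = c(60, 30, 80),
                   height = c(22000, 8000, 400)),
    B = data.frame(center = c(248, 280, 440),
                   fwhm   = c(35, 40, 90),
                   height = c(9000, 4500, 1250))
  )
}

#' Build a toy photoswitch from Gaussian absorption bands
#'
#' @param bands List with data frames `A` and `B`, each with columns
#'   `center` (nm), `fwhm` (nm), `height` (M^-1 cm^-1); default
#'   [azobenzene_like_bands()].
#' @param k_BA Thermal back-isomerization rate constant, s^-1; default
#'   7.2e-7 (azobenzene in methanol at 20 C).
#' @param grid Wavelength grid in nm; default 200-600 nm at 1 nm.
#' @return A `photokin_system`.
#' @export
make_toy_switch <- function(bands = azobenzene_like_bands(),
                            k_BA = 7.2e-7, grid = seq(200, 600, by = 1)) {
  for (iso in c("A", "B")) {
    b <- bands[[iso]]
    stopifnot(is.data.frame(b),
              all(c("center", "fwhm", "height") %in% names(b)))
    if (any(b$height < 0) || any(b$fwhm <= 0))
      .stopf("band heights must be >= 0 and FWHM > 0", class = "photokin_invalid")
  }
  photoswitch_system(
    spectrum_new(grid, .gauss_bands(grid, bands$A), "M-1cm-1", "eps_A"),
    spectrum_new(grid, .gauss_bands(grid, bands$B), "M-1cm-1", "eps_B"),
    k_BA)
}

#' Gaussian LED emission profile
#'
#' Gaussian centered at `center` with the given FWHM, truncated where the
#' intensity falls below 1e-4 of the peak, on a grid fine enough to
#' resolve the band (at least 40 points across the FWHM). An `fwhm` at or
#' below the grid step collapses to a single-bin spike.
#'
#' @param center Peak wavelength, nm.
#' @param fwhm Full width at half maximum, nm, > 0.
#' @param step Grid step in nm; default `min(1, fwhm / 40)`.
#' @return A `photokin_spectrum` with unit `"counts"`, peak value 1.
#' @export
make_led_profile <- function(center, fwhm, step = min(1, fwhm / 40)) {
  if (fwhm <= 0) .stopf("fwhm must be > 0", class = "photokin_invalid")
  if (fwhm <= step) {                   # delta-like single-bin spike
    grid <- center + c(-step, 0, step)
    return(spectrum_new(grid, c(0, 1, 0), "counts",
                        sprintf("LED %g nm (spike)", center)))
  }
  half <- fwhm * sqrt(log(1e4) / (4 * log(2)))  # where it hits 1e-4 of peak
  grid <- seq(center - half, center + half, by = step)
  v <- exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
  v[v < 1e-4] <- 0
  spectrum_new(grid, v, "counts", sprintf("LED %g nm", center))
}

#' Measurement schedule of an irradiation experiment
#'
#' @param duration Total irradiation time in s; default 3600 (1 h).
#' @param interval Spectrum sampling interval in s; default 30.
#' @return Numeric vector of sampling times `0, interval, ..., duration`.
#' @export
irradiation_schedule <- function(duration = 3600, interval = 30) {
  stopifnot(duration > 0, interval > 0, interval <= duration)
  seq(0, duration, by = interval)
}

#' Simulate a noisy in-operando absorbance experiment
#'
#' Integrates the forward model at the true yields and adds i.i.d.
#' Gaussian noise to every absorbance value.
#'
#' @param system A `photokin_system`.
#' @param true_phis A `photokin_qy` (ground truth).
#' @param source A `photokin_source`.
#' @param geometry A `photokin_geometry`.
#' @param initial A `photokin_state`.
#' @param times Sampling times in s; default [irradiation_schedule()].
#' @param wavelengths Spectral grid of the synthetic spectrometer; default
#'   the intersection grid of the two absorptivity spectra.
#' @param noise_sd Absorbance noise standard deviation; default 0.002.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `sts` (noisy `photokin_sts`), `truth` (noiseless
#'   concentration trajectory data frame) and `true_phis`.
#' @export
simulate_noisy_experiment <- function(system, true_phis, source, geometry,
                                      initial,
                                      times = irradiation_schedule(),
                                      wavelengths = NULL, noise_sd = 0.002,
                                      seed = 1L) {
  if (noise_sd < 0) .stopf("noise_sd must be >= 0", class = "photokin_invalid")
  if (is.null(wavelengths)) {
    g <- common_grid(system$eps_A, system$eps_B)
    wavelengths <- g[[1L]]$wavelength
  }
  sim <- simulate_kinetics(system, true_phis, source, geometry, initial,
                           times, wavelengths = wavelengths)
  noisy <- sim$absorbance
  if (noise_sd > 0)
    noisy <- noisy + .with_seed(seed,
      matrix(stats::rnorm(length(noisy), 0, noise_sd), nrow(noisy)))
  spectra <- lapply(seq_along(times), function(i)
    spectrum_new(wavelengths, noisy[i, ], "absorbance",
                 sprintf("t%g", times[i])))
  list(sts = time_series_new(times, spectra), truth = sim$trajectory,
       true_phis = true_phis)
}

#' Synthesize a drifting, noisy thermopile power log
#'
#' Polynomial environmental drift plus a clean step of `p_true` during the
#' LED-on window plus Gaussian read noise.
#'
#' @param p_true LED power at the sensor in W, >= 0.
#' @param baseline_coeffs Polynomial drift coefficients in W (constant
#'   first), evaluated in `t - mean(t)`.
#' @param noise_sd Read-noise standard deviation in W.
#' @param times Sample times in s; default 0-240 s at 0.5 s.
#' @param on_interval LED-on window `[t_start, t_end]`; default
#'   `c(60, 180)`.
#' @param seed Integer seed.
#' @return A `photokin_power_trace` with `on_interval` set.
#' @export
make_power_trace <- function(p_true, baseline_coeffs = c(5e-4, 1e-6),
                             noise_sd = 0, times = seq(0, 240, by = 0.5),
                             on_interval = c(60, 180), seed = 1L) {
  if (p_true < 0) .stopf("p_true must be >= 0", class = "photokin_invalid")
  tc <- times - mean(times)
  drift <- numeric(length(times))
  for (j in seq_along(baseline_coeffs))
    drift <- drift + baseline_coeffs[j] * tc^(j - 1)
  p <- drift + ifelse(times >= on_interval[1L] & times <= on_interval[2L],
                      p_true, 0)
  if (noise_sd > 0)
    p <- p + .with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  power_trace_new(times, p, on_interval)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Produces, in the dialects the package's readers accept: the two
#' absorptivity spectra, the LED emission file, a noisy wide-format
#' absorbance time series, a power log, a YAML run config pointing at
#' them, and a ground-truth key-value file. Byte-identical for identical
#' arguments and seed.
#'
#' @param dir Output directory (created if missing).
#' @param true_phis Ground-truth `photokin_qy`; default
#'   `quantum_yields(0.16, 0.38)`.
#' @param p_true LED power at the sample in W; default 1e-3.
#' @param led_center,led_fwhm LED peak and width in nm; defaults 340, 10.
#' @param total_conc Total concentration in M; default sized so the
#'   initial absorbance at the excitation peak is 0.9.
#' @param noise_sd Absorbance noise; default 0.002.
#' @param power_noise_sd Power-log noise in W; default 2e-5.
#' @param seed Integer seed.
#' @return The directory path, invisibly; side effect: files written.
#' @export
generate_fixture_set <- function(dir, true_phis = quantum_yields(0.16, 0.38),
                                 p_true = 1e-3, led_center = 340,
                                 led_fwhm = 10, total_conc = NULL,
                                 noise_sd = 0.002, power_noise_sd = 2e-5,
                                 seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  system <- make_toy_switch()
  geometry <- experiment_geometry()
  if (is.null(total_conc))
    total_conc <- 0.9 / (interpolate_spectrum(system$eps_A, led_center) *
                           geometry$path_probe)
  led <- make_led_profile(led_center, led_fwhm)
  source <- photon_flux(power_result_new(p_true, 0), emission = led)
  initial <- kinetic_state(total_conc, 0)
  times <- irradiation_schedule()
  exp_ <- simulate_noisy_experiment(system, true_phis, source, geometry,
                                    initial, times, noise_sd = noise_sd,
                                    seed = seed)
  trace <- make_power_trace(p_true, noise_sd = power_noise_sd,
                            seed = seed + 1L)

  write_spectrum(system$eps_A, file.path(dir, "eps_A.csv"))
  write_spectrum(system$eps_B, file.path(dir, "eps_B.csv"))
  write_spectrum(led, file.path(dir, "led_emission.csv"))
  write_time_series(exp_$sts, file.path(dir, "timeseries.csv"))
  utils::write.csv(data.frame(time_s = trace$times,
                              power_W = trace$power),
                   file.path(dir, "power.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(c(sprintf("phi_AB=%.10g", true_phis$phi_AB),
               sprintf("phi_BA=%.10g", true_phis$phi_BA),
               sprintf("p_true_W=%.10g", p_true),
               sprintf("total_conc_M=%.10g", total_conc),
               sprintf("seed=%d", seed)),
             file.path(dir, "ground_truth.txt"))
  cfg <- c(
    "mode: integrated-emission",
    "eps_A: eps_A.csv", "eps_B: eps_B.csv",
    "emission: led_emission.csv",
    "timeseries: timeseries.csv",
    "power_logs: [power.csv]",
    sprintf("on_start: %g", trace$on_interval[1L]),
    sprintf("on_end: %g", trace$on_interval[2L]),
    sprintf("excitation_nm: %g", led_center),
    sprintf("volume_L: %g", geometry$volume),
    sprintf("path_irradiation_cm: %g", geometry$path_irradiation),
    sprintf("path_probe_cm: %g", geometry$path_probe),
    sprintf("k_BA: %g", system$k_BA),
    sprintf("temperature_C: %g", geometry$temperature),
    sprintf("seed: %d", seed))
  writeLines(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
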