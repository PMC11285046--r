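# Thermopile power logs -> photon flux with uncertainty.
#
# Pipeline: subtract_baseline() removes slow environmental drift (fit to
# LED-off samples only), average_on_power() averages the LED-on plateau,
# correct_transmission_loss() applies the half-of-total-loss cuvette
# correction, weighted_mean_power() pools replicate determinations by
# inverse variance, photon_flux() converts watts to photons per second.

#' Construct a power trace
#'
#' @param times Sample times in s, strictly increasing.
#' @param power Power readings in W, finite.
#' @param on_interval Length-2 numeric `[t_start, t_end]` marking LED-on,
#'   inside the time range, or `NULL` (detect later).
#' @return A `photokin_power_trace`.
#' @export
power_trace_new <- function(times, power, on_interval = NULL) {
  times <- as.numeric(times); power <- as.numeric(power)
  if (length(times) != length(power))
    .stopf("times (%d) and power (%d) lengths differ", length(times),
           length(power), class = "photokin_invalid")
  if (length(times) < 2L || any(diff(times) <= 0))
    .stopf("times must be strictly increasing, length >= 2",
           class = "photokin_invalid")
  if (!all(is.finite(power)))
    .stopf("power values must be finite", class = "photokin_invalid")
  if (!is.null(on_interval)) {
    on_interval <- as.numeric(on_interval)
    if (length(on_interval) != 2L || on_interval[1L] >= on_interval[2L] ||
        on_interval[1L] < times[1L] || on_interval[2L] > times[length(times)])
      .stopf("on_interval must satisfy times[1] <= t_start < t_end <= times[n]",
             class = "photokin_invalid")
  }
  structure(list(times = times, power = power, on_interval = on_interval,
                 baseline_subtracted = FALSE),
            class = "photokin_power_trace")
}

#' @export
print.photokin_power_trace <- function(x, ...) {
  on <- if (is.null(x$on_interval)) "undetected"
        else sprintf("[%g, %g] s", x$on_interval[1L], x$on_interval[2L])
  cat(sprintf("<power trace: %d samples over %g s, on-interval %s%s>\n",
              length(x$times), diff(range(x$times)), on,
              if (x$baseline_subtracted) ", baseline-subtracted" else ""))
  invisible(x)
}

.on_mask <- function(trace) {
  if (is.null(trace$on_interval))
    .stopf("trace has no on_interval; supply one or run detect_on_interval()",
           class = "photokin_invalid")
  trace$times >= trace$on_interval[1L] & trace$times <= trace$on_interval[2L]
}

#' Auto-detect the LED-on window of a power trace
#'
#' Finds the longest contiguous run of samples above
#' `baseline + 5 * off-segment std`, where the baseline level and off-segment
#' scatter are first estimated robustly (median and MAD of the whole trace,
#' then refined on the below-threshold samples).
#'
#' @param trace A `photokin_power_trace`.
#' @return The trace with `on_interval` filled in.
#' @export
detect_on_interval <- function(trace) {
  stopifnot(inherits(trace, "photokin_power_trace"))
  p <- trace$power
  # provisional split at the midpoint of the (spike-resistant) range,
  # then refine baseline level and scatter on the provisional off set
  qs <- stats::quantile(p, c(0.02, 0.98), names = FALSE)
  off <- p <= (qs[1L] + qs[2L]) / 2
  if (!any(off) || all(off))
    .stopf("no samples above baseline + 5 sd; cannot detect LED-on window",
           class = "photokin_detect")
  base <- mean(p[off])
  sd0 <- stats::sd(p[off])
  if (!is.finite(sd0) || sd0 == 0) sd0 <- stats::sd(p) * 1e-3 + 1e-15
  above <- p > base + 5 * sd0
  if (sum(above) < 4L)
    .stopf("no clear plateau above baseline + 5 sd; cannot detect LED-on window",
           class = "photokin_detect")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  if (sum(r$values & r$lengths == r$lengths[best]) > 1L)
    .stopf("LED-on detection ambiguous: several equally long above-threshold runs",
           class = "photokin_detect")
  trace$on_interval <- c(trace$times[starts[best]], trace$times[ends[best]])
  trace
}

#' Subtract a polynomial baseline fitted to LED-off samples
#'
#' Fits a polynomial of the given degree to all samples outside the
#' on-interval (before and, when the log continues past LED-off, after) and
#' subtracts it from the whole trace, leaving the LED-off residual mean at
#' zero and the on-segment at the net LED power.
#'
#' @param trace A `photokin_power_trace` with a known `on_interval`.
#' @param degree Polynomial degree, 0-3; default 1 (linear drift).
#' @return The corrected `photokin_power_trace`.
#' @export
subtract_baseline <- function(trace, degree = 1L) {
  stopifnot(inherits(trace, "photokin_power_trace"))
  degree <- as.integer(degree)
  if (degree < 0L || degree > 3L)
    .stopf("baseline degree must be 0-3, got %d", degree,
           class = "photokin_invalid")
  off <- !.on_mask(trace)
  if (sum(off) < degree + 2L)
    .stopf("only %d LED-off samples; need >= %d for a degree-%d baseline",
           sum(off), degree + 2L, degree, class = "photokin_baseline")
  t0 <- mean(trace$times[off])           # center for conditioning
  x <- (trace$times - t0) / max(1, diff(range(trace$times)))
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X[off, , drop = FALSE], trace$power[off])
  trace$power <- trace$power - as.numeric(X %*% fit$coefficients)
  trace$baseline_subtracted <- TRUE
  trace
}

#' Construct a power result
#'
#' @param mean_power Mean power in W.
#' @param std_power Uncertainty in W, >= 0.
#' @param n_samples Number of samples averaged.
#' @param correction_applied Whether the transmission-loss correction has
#'   been applied.
#' @return A `photokin_power_result`.
#' @export
power_result_new <- function(mean_power, std_power, n_samples = 1L,
                             correction_applied = FALSE) {
  if (std_power < 0)
    .stopf("std_power must be >= 0", class = "photokin_invalid")
  structure(list(mean_power = mean_power, std_power = std_power,
                 n_samples = as.integer(n_samples),
                 correction_applied = isTRUE(correction_applied)),
            class = "photokin_power_result")
}

#' @export
print.photokin_power_result <- function(x, ...) {
  cat(sprintf("<power: %.6g +/- %.3g W (n = %d%s)>\n", x$mean_power,
              x$std_power, x$n_samples,
              if (x$correction_applied) ", loss-corrected" else ""))
  invisible(x)
}

#' Average the LED-on plateau of a baseline-subtracted trace
#'
#' Discards the first `settle_time` seconds of the on-window (thermopile
#' thermal rise), then reports mean and sample standard deviation.
#'
#' @param trace A corrected `photokin_power_trace`.
#' @param settle_time Seconds of the on-window to discard; default 5.
#' @return A `photokin_power_result`.
#' @export
average_on_power <- function(trace, settle_time = 5) {
  stopifnot(inherits(trace, "photokin_power_trace"))
  on <- trace$on_interval
  if (is.null(on)) .on_mask(trace)  # raises the standard error
  if (diff(on) <= settle_time)
    .stopf("on-interval (%g s) not longer than settle_time (%g s)",
           diff(on), settle_time, class = "photokin_invalid")
  keep <- trace$times >= on[1L] + settle_time & trace$times <= on[2L]
  if (!any(keep))
    .stopf("no samples left in the on-window after the settle time",
           class = "photokin_invalid")
  p <- trace$power[keep]
  power_result_new(mean(p), if (length(p) > 1L) stats::sd(p) else 0,
                   length(p))
}

#' Correct the LED power for transmission losses at the sample
#'
#' The bare-path power and the power transmitted through jacket + cuvette
#' differ by the total optical loss; the loss at the sample position is
#' taken as a fraction (default one half) of that total:
#' `P_sample = P_bare - loss_fraction * (P_bare - P_through)`. Uncertainties
#' combine in quadrature with the same weights.
#'
#' @param p_bare Power without optical elements (`photokin_power_result`).
#' @param p_through Power through jacket and solvent-filled cuvette.
#' @param loss_fraction_at_sample Fraction of the total loss occurring
#'   before the sample; default 0.5.
#' @return A `photokin_power_result` with `correction_applied = TRUE`.
#' @export
correct_transmission_loss <- function(p_bare, p_through,
                                      loss_fraction_at_sample = 0.5) {
  stopifnot(inherits(p_bare, "photokin_power_result"),
            inherits(p_through, "photokin_power_result"))
  f <- loss_fraction_at_sample
  if (f < 0 || f > 1)
    .stopf("loss_fraction_at_sample must be in [0, 1]", class = "photokin_invalid")
  if (p_through$mean_power > p_bare$mean_power)
    .stopf("transmitted power (%g W) exceeds bare power (%g W): physically inconsistent",
           p_through$mean_power, p_bare$mean_power, class = "photokin_physical")
  if (p_through$mean_power < 0)
    .stopf("transmitted power must be >= 0", class = "photokin_physical")
  mean_p <- p_bare$mean_power -
    f * (p_bare$mean_power - p_through$mean_power)
  std_p <- sqrt(((1 - f) * p_bare$std_power)^2 + (f * p_through$std_power)^2)
  power_result_new(mean_p, std_p,
                   min(p_bare$n_samples, p_through$n_samples),
                   correction_applied = TRUE)
}

#' Inverse-variance weighted mean of replicate power determinations
#'
#' Pools replicates with weights `w_i = 1 / std_i^2`; the pooled
#' uncertainty is `sqrt(1 / sum(w_i))`. If every replicate reports zero
#' uncertainty the plain mean is returned with zero uncertainty; a mixture
#' of zero and nonzero uncertainties is ambiguous and rejected.
#'
#' @param results List of `photokin_power_result`.
#' @return A `photokin_power_result`.
#' @export
weighted_mean_power <- function(results) {
  if (inherits(results, "photokin_power_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  lapply(results, function(r)
    stopifnot(inherits(r, "photokin_power_result")))
  if (length(results) == 1L) return(results[[1L]])
  m <- vapply(results, function(r) r$mean_power, 0)
  s <- vapply(results, function(r) r$std_power, 0)
  corr <- any(vapply(results, function(r) r$correction_applied, NA))
  n <- sum(vapply(results, function(r) r$n_samples, 0L))
  if (all(s == 0)) return(power_result_new(mean(m), 0, n, corr))
  if (any(s == 0))
    .stopf("mixed zero and nonzero uncertainties; supply explicit weights by setting nonzero std on every replicate",
           class = "photokin_ambiguous")
  w <- 1 / s^2
  power_result_new(sum(w * m) / sum(w), sqrt(1 / sum(w)), n, corr)
}

#' Construct a monochromatic irradiation source
#'
#' @param q0 Photon flux in photons s^-1, >= 0.
#' @param wavelength Excitation wavelength in nm, > 0.
#' @return A `photokin_source` with `mode = "monochromatic"`.
#' @export
monochromatic_source <- function(q0, wavelength) {
  if (q0 < 0) .stopf("photon flux must be >= 0", class = "photokin_invalid")
  if (wavelength <= 0)
    .stopf("wavelength must be positive", class = "photokin_invalid")
  structure(list(q0 = q0, mode = "monochromatic", wavelength = wavelength,
                 f = NULL),
            class = "photokin_source")
}

#' Construct a polychromatic (emission-spectrum) irradiation source
#'
#' `f` must already be on a photon basis; it is renormalized so that its
#' trapezoid-rule integral over wavelength is exactly 1.
#'
#' @param q0 Total photon flux in photons s^-1.
#' @param f Emission distribution (`photokin_spectrum`, unit `"counts"`),
#'   non-negative, photon basis.
#' @return A `photokin_source` with `mode = "polychromatic"`.
#' @export
polychromatic_source <- function(q0, f) {
  if (q0 < 0) .stopf("photon flux must be >= 0", class = "photokin_invalid")
  stopifnot(inherits(f, "photokin_spectrum"))
  area <- .trapz(f$wavelength, f$value)
  if (area <= 0)
    .stopf("emission distribution integrates to zero", class = "photokin_invalid")
  f$value <- f$value / area
  structure(list(q0 = q0, mode = "polychromatic", wavelength = NULL, f = f),
            class = "photokin_source")
}

#' @export
print.photokin_source <- function(x, ...) {
  if (x$mode == "monochromatic")
    cat(sprintf("<source: monochromatic %g nm, q0 = %.4g photons/s>\n",
                x$wavelength, x$q0))
  else
    cat(sprintf("<source: polychromatic (%d-point emission, %.1f-%.1f nm), q0 = %.4g photons/s>\n",
                length(x$f$wavelength), min(x$f$wavelength),
                max(x$f$wavelength), x$q0))
  invisible(x)
}

#' Convert a measured power to a photon flux
#'
#' Monochromatic: `q0 = P * lambda / (h * c)`. Polychromatic: the measured
#' emission intensity `g(lambda)` is read on a power basis (J s^-1 nm^-1,
#' relative), converted per wavelength to a photon basis
#' `phi(lambda) = K * g(lambda) * lambda` with `K` chosen so that the total
#' radiant power `integral(phi * h c / lambda)` equals the measured power;
#' then `q0 = integral(phi)` and `f = phi / q0`. Spectrometer irradiance
#' calibrations report power basis; if the emission file is already photon
#' basis set `emission_basis = "photon"` to skip the lambda weighting.
#'
#' @param power A `photokin_power_result` (or a single power in W).
#' @param wavelength Excitation wavelength in nm (monochromatic mode).
#' @param emission Measured LED emission spectrum (polychromatic mode).
#' @param emission_basis `"power"` (default) or `"photon"`.
#' @return A `photokin_source`. The relative power uncertainty is carried
#'   along as attribute `"rel_uncertainty"` for downstream propagation.
#' @export
photon_flux <- function(power, wavelength = NULL, emission = NULL,
                        emission_basis = c("power", "photon")) {
  emission_basis <- match.arg(emission_basis)
  if (is.numeric(power)) power <- power_result_new(power, 0)
  stopifnot(inherits(power, "photokin_power_result"))
  P <- power$mean_power
  if (P < 0) .stopf("power must be >= 0", class = "photokin_invalid")
  if (is.null(emission)) {
    if (is.null(wavelength))
      .stopf("monochromatic mode needs an excitation wavelength",
             class = "photokin_invalid")
    if (wavelength <= 0)
      .stopf("wavelength must be positive", class = "photokin_invalid")
    q0 <- P / .photon_energy(wavelength)
    src <- monochromatic_source(q0, wavelength)
  } else {
    stopifnot(inherits(emission, "photokin_spectrum"))
    if (all(emission$value == 0))
      .stopf("emission spectrum is identically zero", class = "photokin_invalid")
    w <- emission$wavelength
    phi <- if (emission_basis == "power") emission$value * w
           else emission$value
    pow_per_photon <- .photon_energy(w)          # J per photon at each node
    K <- P / .trapz(w, phi * pow_per_photon)
    phi <- K * phi
    q0 <- .trapz(w, phi)
    src <- polychromatic_source(q0, spectrum_new(w, phi, "counts",
                                                 emission$label))
  }
  attr(src, "rel_uncertainty") <-
    if (P > 0) power$std_power / P else 0
  src
}

#' Rescale a source's photon flux
#'
#' Used by the power-limit uncertainty propagation: the photon flux is
#' linear in the measured power, so the min/max-power refits reuse the same
#' spectral distribution with a scaled `q0`.
#'
#' @param source A `photokin_source`.
#' @param factor Multiplicative factor, >= 0.
#' @return The rescaled source.
#' @export
scale_source <- function(source, factor) {
  stopifnot(inherits(source, "photokin_source"), factor >= 0)
  source$q0 <- source$q0 * factor
  source
}
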