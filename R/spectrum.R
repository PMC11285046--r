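#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed vector of values carrying a unit tag:
#' dimensionless absorbance, molar absorptivity in M^-1 cm^-1, or relative
#' emission intensity ("counts"). The wavelength grid must be strictly
#' increasing and positive; absorptivity and emission values must be
#' non-negative.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, all positive, length >= 2.
#' @param value Numeric vector of the same length as `wavelength`.
#' @param unit One of `"absorbance"`, `"M-1cm-1"`, `"counts"`.
#' @param label Free-text label carried through I/O.
#' @return An object of class `photokin_spectrum`.
#' @examples
#' sp <- spectrum_new(c(300, 310, 320), c(0.1, 0.4, 0.9), "absorbance")
#' interpolate_spectrum(sp, 315)
#' @export
spectrum_new <- function(wavelength, value, unit = c("absorbance", "M-1cm-1", "counts"),
                         label = "") {
  unit <- match.arg(unit)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    .stopf("wavelength (%d) and value (%d) lengths differ",
           length(wavelength), length(value), class = "photokin_invalid")
  if (length(wavelength) < 2L)
    .stopf("a spectrum needs at least 2 points, got %d", length(wavelength),
           class = "photokin_invalid")
  if (anyNA(wavelength) || anyNA(value))
    .stopf("NA values in spectrum", class = "photokin_invalid")
  if (any(wavelength <= 0))
    .stopf("wavelengths must be positive", class = "photokin_invalid")
  if (any(diff(wavelength) <= 0)) {
    bad <- which(diff(wavelength) <= 0)[1L]
    .stopf("wavelength grid not strictly increasing at index %d (%g nm)",
           bad + 1L, wavelength[bad + 1L], class = "photokin_monotonicity")
  }
  if (unit != "absorbance" && any(value < 0))
    .stopf("%s values must be non-negative", unit, class = "photokin_invalid")
  structure(list(wavelength = wavelength, value = value, unit = unit,
                 label = label),
            class = "photokin_spectrum")
}

#' @export
print.photokin_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum%s: %d points, %.1f-%.1f nm, unit = %s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$unit))
  invisible(x)
}

#' Linear interpolation of a spectrum
#'
#' Exact at grid nodes; errors on queries outside the grid range rather
#' than extrapolating.
#'
#' @param spectrum A `photokin_spectrum`.
#' @param wavelength Query wavelengths in nm, all within the grid range.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_spectrum <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "photokin_spectrum"))
  rng <- range(spectrum$wavelength)
  out <- wavelength < rng[1L] | wavelength > rng[2L]
  if (any(out))
    .stopf("query wavelength %g nm outside spectrum range [%g, %g] nm",
           wavelength[out][1L], rng[1L], rng[2L], class = "photokin_range")
  stats::approx(spectrum$wavelength, spectrum$value, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Resample several spectra onto a common wavelength grid
#'
#' The common grid is the union of the input grids restricted to the
#' intersection of their ranges, so no spectrum is extrapolated.
#'
#' @param ... `photokin_spectrum` objects.
#' @return List of spectra sharing one grid, in input order.
#' @export
common_grid <- function(...) {
  sps <- list(...)
  if (length(sps) == 1L && is.list(sps[[1L]]) &&
      !inherits(sps[[1L]], "photokin_spectrum")) sps <- sps[[1L]]
  lapply(sps, function(s) stopifnot(inherits(s, "photokin_spectrum")))
  lo <- max(vapply(sps, function(s) min(s$wavelength), 0))
  hi <- min(vapply(sps, function(s) max(s$wavelength), 0))
  if (lo >= hi)
    .stopf("spectra share no wavelength overlap ([%g, %g] nm empty)", lo, hi,
           class = "photokin_range")
  grid <- sort(unique(unlist(lapply(sps, function(s) s$wavelength))))
  grid <- grid[grid >= lo & grid <= hi]
  lapply(sps, function(s)
    spectrum_new(grid, interpolate_spectrum(s, grid), s$unit, s$label))
}

#' Two-component mixture decomposition of an absorbance spectrum
#'
#' Models an observed spectrum as `c * pure_A + (1 - c) * pure_B` with the
#' two pure-isomer spectra taken at the sample's total concentration, and
#' returns the mole fraction `c` of component A minimizing the residual sum
#' of squares over `fit_range`. Solved in closed form as one-parameter
#' linear least squares; the estimate is clipped to `[0, 1]`.
#'
#' @param observed,pure_A,pure_B Absorbance spectra (`photokin_spectrum`).
#' @param fit_range Length-2 numeric, wavelength interval (nm) over which
#'   the residual is minimized. Required: the informative range depends on
#'   the switch and irradiation band.
#' @return List with elements `fraction_A`, `residual_norm` (L2 norm of the
#'   residual at the clipped optimum) and `n_points`.
#' @export
decompose_mixture <- function(observed, pure_A, pure_B, fit_range) {
  stopifnot(length(fit_range) == 2L, fit_range[1L] < fit_range[2L])
  sps <- common_grid(observed, pure_A, pure_B)
  keep <- sps[[1L]]$wavelength >= fit_range[1L] &
    sps[[1L]]$wavelength <= fit_range[2L]
  if (sum(keep) < 2L)
    .stopf("fit_range [%g, %g] nm covers fewer than 2 common grid points",
           fit_range[1L], fit_range[2L], class = "photokin_range")
  obs <- sps[[1L]]$value[keep]
  a <- sps[[2L]]$value[keep]
  b <- sps[[3L]]$value[keep]
  d <- a - b
  denom <- sum(d * d)
  if (denom <= .Machine$double.eps * sum(a * a + b * b))
    .stopf("pure spectra are collinear over the fit range; c is not identifiable",
           class = "photokin_degenerate")
  cc <- sum(d * (obs - b)) / denom
  cc <- min(1, max(0, cc))
  res <- obs - (cc * a + (1 - cc) * b)
  list(fraction_A = cc, residual_norm = sqrt(sum(res * res)),
       n_points = sum(keep))
}

#' Construct a spectral time series
#'
#' An ordered collection of absorbance spectra on one shared wavelength
#' grid, stamped with cumulative irradiation time in seconds.
#'
#' @param times Numeric vector, strictly increasing, `times[1] >= 0`.
#' @param spectra List of `photokin_spectrum`, one per time, sharing a grid.
#' @return An object of class `photokin_sts`.
#' @export
time_series_new <- function(times, spectra) {
  times <- as.numeric(times)
  if (length(times) != length(spectra))
    .stopf("times (%d) and spectra (%d) lengths differ",
           length(times), length(spectra), class = "photokin_invalid")
  if (length(times) < 1L || times[1L] < 0 || any(diff(times) <= 0))
    .stopf("times must be strictly increasing and start at >= 0",
           class = "photokin_invalid")
  grid <- spectra[[1L]]$wavelength
  for (s in spectra) {
    stopifnot(inherits(s, "photokin_spectrum"))
    if (length(s$wavelength) != length(grid) || any(s$wavelength != grid))
      .stopf("all spectra in a time series must share one wavelength grid",
             class = "photokin_invalid")
  }
  structure(list(times = times, wavelength = grid,
                 absorbance = vapply(spectra, function(s) s$value,
                                     numeric(length(grid)))),
            class = "photokin_sts")
}

#' @export
print.photokin_sts <- function(x, ...) {
  cat(sprintf("<spectral time series: %d spectra, t = %g-%g s, %d wavelengths (%.1f-%.1f nm)>\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Extract the absorbance-vs-time trace at one wavelength
#'
#' @param sts A `photokin_sts`.
#' @param wavelength Single wavelength in nm (interpolated on the grid).
#' @return Data frame with columns `time_s`, `absorbance`.
#' @export
absorbance_trace <- function(sts, wavelength) {
  stopifnot(inherits(sts, "photokin_sts"), length(wavelength) == 1L)
  rng <- range(sts$wavelength)
  if (wavelength < rng[1L] || wavelength > rng[2L])
    .stopf("wavelength %g nm outside grid range [%g, %g] nm",
           wavelength, rng[1L], rng[2L], class = "photokin_range")
  abs_t <- apply(sts$absorbance, 2L, function(v)
    stats::approx(sts$wavelength, v, xout = wavelength)$y)
  data.frame(time_s = sts$times, absorbance = abs_t)
}
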