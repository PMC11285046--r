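# Photokinetics of a two-state photoswitch A <-> B.
#
# d[A]/dt = (q0 / (N_A V)) * F(Abs_tot) *
#             (Phi_BA [B] eps_B l - Phi_AB [A] eps_A l) + k_BA [B]
# d[B]/dt = -d[A]/dt
#
# with Abs_tot = ([A] eps_A + [B] eps_B) l the decadic absorbance along the
# irradiation path and F(x) = (1 - 10^-x) / x the inner-filter factor
# (F -> ln 10 as x -> 0). For an LED with emission distribution f(lambda)
# (photon-normalized) the photochemical term is integrated over wavelength
# with per-wavelength absorbed fraction 1 - 10^-Abs_tot(lambda).

#' Construct a photoswitch system
#'
#' Holds the molar absorptivity spectra of the stable isomer A (e.g.
#' trans) and the metastable isomer B (e.g. cis) plus the thermal B->A
#' rate constant.
#'
#' @param eps_A,eps_B Molar absorptivity spectra (`photokin_spectrum`,
#'   unit `"M-1cm-1"`).
#' @param k_BA Thermal back-isomerization rate constant in s^-1, >= 0.
#' @return A `photokin_system`.
#' @export
photoswitch_system <- function(eps_A, eps_B, k_BA = 0) {
  stopifnot(inherits(eps_A, "photokin_spectrum"),
            inherits(eps_B, "photokin_spectrum"))
  if (eps_A$unit != "M-1cm-1" || eps_B$unit != "M-1cm-1")
    .stopf("eps_A and eps_B must carry unit 'M-1cm-1'", class = "photokin_invalid")
  if (k_BA < 0) .stopf("k_BA must be >= 0", class = "photokin_invalid")
  structure(list(eps_A = eps_A, eps_B = eps_B, k_BA = k_BA),
            class = "photokin_system")
}

#' @export
print.photokin_system <- function(x, ...) {
  cat(sprintf("<photoswitch system: eps_A %.0f-%.0f nm, eps_B %.0f-%.0f nm, k_BA = %g s^-1>\n",
              min(x$eps_A$wavelength), max(x$eps_A$wavelength),
              min(x$eps_B$wavelength), max(x$eps_B$wavelength), x$k_BA))
  invisible(x)
}

#' Construct a quantum-yield pair
#'
#' @param phi_AB Forward (A -> B) photoisomerization quantum yield, in
#'   `[0, 1]`.
#' @param phi_BA Backward (B -> A) quantum yield, in `[0, 1]`.
#' @return A `photokin_qy` with fields `phi_AB`, `phi_BA`.
#' @export
quantum_yields <- function(phi_AB, phi_BA) {
  if (phi_AB < 0 || phi_AB > 1 || phi_BA < 0 || phi_BA > 1)
    .stopf("quantum yields must lie in [0, 1]", class = "photokin_invalid")
  structure(list(phi_AB = phi_AB, phi_BA = phi_BA), class = "photokin_qy")
}

#' Construct the experiment geometry
#'
#' @param path_irradiation Optical path along the irradiation direction,
#'   cm; drives the photochemistry.
#' @param path_probe Optical path along the (perpendicular) probe
#'   direction, cm; sets the reported absorbance.
#' @param volume Sample volume in L.
#' @param temperature Sample temperature in degrees C (metadata only).
#' @return A `photokin_geometry`.
#' @export
experiment_geometry <- function(path_irradiation = 1, path_probe = 1,
                                volume = 3e-3, temperature = 20) {
  if (path_irradiation <= 0 || path_probe <= 0 || volume <= 0)
    .stopf("path lengths and volume must be positive", class = "photokin_invalid")
  structure(list(path_irradiation = path_irradiation,
                 path_probe = path_probe, volume = volume,
                 temperature = temperature),
            class = "photokin_geometry")
}

#' Construct a kinetic state
#'
#' @param conc_A,conc_B Concentrations in M, >= 0.
#' @param time Time stamp in s.
#' @return A `photokin_state`.
#' @export
kinetic_state <- function(conc_A, conc_B, time = 0) {
  if (conc_A < 0 || conc_B < 0)
    .stopf("concentrations must be >= 0", class = "photokin_invalid")
  structure(list(conc_A = conc_A, conc_B = conc_B, time = time),
            class = "photokin_state")
}

#' Fraction of incident photons absorbed along the irradiation path
#'
#' `1 - 10^(-Abs)` for a decadic absorbance `Abs >= 0`.
#'
#' @param abs_total Decadic absorbance along the irradiation path.
#' @return Value in `[0, 1)`.
#' @export
absorbed_fraction <- function(abs_total) {
  if (any(abs_total < 0))
    .stopf("absorbance must be >= 0", class = "photokin_invalid")
  -expm1(-abs_total * log(10))
}

# (1 - 10^-x)/x, continuous at x = 0 where it equals ln 10; expm1 keeps
# the quotient accurate for small x
.inner_filter_factor <- function(x) {
  ifelse(x > 0, -expm1(-x * log(10)) / x, log(10))
}

#' Partition of absorbed photons between the two species
#'
#' Each species absorbs in proportion to its share of the total
#' absorbance: `share_X = Abs_X / (Abs_A + Abs_B)`. The photon uptake of
#' species X is then `q_X = q0 * share_X * absorbed_fraction(Abs_tot)`.
#'
#' @param abs_A,abs_B Decadic absorbances of the two species, >= 0, not
#'   both zero.
#' @return Named numeric `c(share_A, share_B)`, summing to 1.
#' @export
species_photon_share <- function(abs_A, abs_B) {
  if (abs_A < 0 || abs_B < 0)
    .stopf("absorbances must be >= 0", class = "photokin_invalid")
  tot <- abs_A + abs_B
  if (tot == 0)
    .stopf("both species absorbances are zero: no photons absorbed",
           class = "photokin_degenerate")
  c(share_A = abs_A / tot, share_B = abs_B / tot)
}

# Internal: full dA/dt for given concentrations and yields, using a
# precomputed wavelength context (everything spectral is interpolated once
# per (system, source, geometry) so the ODE right-hand side stays cheap).
.rate_dA <- function(cA, cB, phis, ctx) {
  if (ctx$mode == "monochromatic") {
    abs_tot <- (cA * ctx$eA + cB * ctx$eB) * ctx$l
    ctx$pre * .inner_filter_factor(abs_tot) * ctx$l *
      (phis$phi_BA * cB * ctx$eB - phis$phi_AB * cA * ctx$eA) +
      ctx$k * cB
  } else {
    abs_tot <- (cA * ctx$eA + cB * ctx$eB) * ctx$l
    integrand <- ctx$f * .inner_filter_factor(abs_tot) * ctx$l *
      (phis$phi_BA * cB * ctx$eB - phis$phi_AB * cA * ctx$eA)
    ctx$pre * .trapz(ctx$grid, integrand) + ctx$k * cB
  }
}

# Build the context list used by .rate_dA
.rate_context <- function(system, source, geometry, thermal = TRUE) {
  l <- geometry$path_irradiation
  pre <- source$q0 / (physical_constants$N_A * geometry$volume)
  k <- if (thermal) system$k_BA else 0
  if (source$mode == "monochromatic") {
    list(mode = "monochromatic", l = l, pre = pre, k = k,
         eA = interpolate_spectrum(system$eps_A, source$wavelength),
         eB = interpolate_spectrum(system$eps_B, source$wavelength))
  } else {
    ovl <- common_grid(source$f, system$eps_A, system$eps_B)
    w <- ovl[[1L]]$wavelength
    f <- ovl[[1L]]$value
    keep <- f >= 1e-4 * max(f)
    if (sum(keep) < 2L)
      .stopf("emission and absorptivity spectra share no usable overlap",
             class = "photokin_range")
    w <- w[keep]; f <- f[keep]
    f <- f / .trapz(w, f)
    list(mode = "polychromatic", l = l, pre = pre, k = k, grid = w, f = f,
         eA = ovl[[2L]]$value[keep], eB = ovl[[3L]]$value[keep])
  }
}

#' Instantaneous rates under monochromatic irradiation
#'
#' @param state A `photokin_state`.
#' @param system A `photokin_system`.
#' @param phis A `photokin_qy`.
#' @param source A monochromatic `photokin_source`.
#' @param geometry A `photokin_geometry`.
#' @param thermal Include the thermal B->A term (default `TRUE`).
#' @return Named numeric `c(dA_dt, dB_dt)` in M s^-1, with
#'   `dB_dt = -dA_dt`.
#' @export
rate_monochromatic <- function(state, system, phis, source, geometry,
                               thermal = TRUE) {
  stopifnot(inherits(state, "photokin_state"),
            source$mode == "monochromatic")
  ctx <- .rate_context(system, source, geometry, thermal)
  dA <- .rate_dA(state$conc_A, state$conc_B, phis, ctx)
  c(dA_dt = dA, dB_dt = -dA)
}

#' Instantaneous rates under an LED emission distribution
#'
#' Integrates the monochromatic rate law over the source's
#' photon-normalized emission distribution by the trapezoid rule on the
#' intersection of the emission and absorptivity grids. The thermal term
#' is included by default for consistency with the monochromatic law;
#' `thermal = FALSE` gives the purely photochemical form.
#'
#' @inheritParams rate_monochromatic
#' @param source A polychromatic `photokin_source`.
#' @return Named numeric `c(dA_dt, dB_dt)` in M s^-1.
#' @export
rate_polychromatic <- function(state, system, phis, source, geometry,
                               thermal = TRUE) {
  stopifnot(inherits(state, "photokin_state"),
            source$mode == "polychromatic")
  ctx <- .rate_context(system, source, geometry, thermal)
  dA <- .rate_dA(state$conc_A, state$conc_B, phis, ctx)
  c(dA_dt = dA, dB_dt = -dA)
}

#' Integrate the photokinetic rate equations
#'
#' Adaptive stiff-capable integration (deSolve's lsoda) of the two-state
#' system from an initial state to the requested output times.
#'
#' @inheritParams rate_monochromatic
#' @param initial A `photokin_state` giving the concentrations at `times[1]`
#'   (or at 0 if `times` starts later).
#' @param times Strictly increasing output times in s.
#' @param wavelengths Optional wavelengths (nm) at which probe-path model
#'   absorbance is evaluated for every output time.
#' @param rtol,atol Solver tolerances (defaults 1e-8 relative, 1e-12 M
#'   absolute).
#' @return List with `trajectory` (data frame `time`, `conc_A`, `conc_B`)
#'   and, when `wavelengths` is given, `absorbance` (matrix, time x
#'   wavelength) plus the `wavelengths` themselves.
#' @export
simulate_kinetics <- function(system, phis, source, geometry, initial,
                              times, wavelengths = NULL, thermal = TRUE,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(initial, "photokin_state"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0))
    .stopf("output times must be strictly increasing", class = "photokin_invalid")
  ctx <- .rate_context(system, source, geometry, thermal)
  t0 <- initial$time
  prepend <- times[1L] > t0
  tt <- if (prepend) c(t0, times) else times
  if (tt[1L] < t0)
    .stopf("output times start before the initial state (t = %g s)", t0,
           class = "photokin_invalid")
  rhs <- function(t, y, p) {
    dA <- .rate_dA(y[1L], y[2L], phis, ctx)
    list(c(dA, -dA))
  }
  sol <- deSolve::ode(y = c(A = initial$conc_A, B = initial$conc_B),
                      times = tt, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")[1L]
  if (is.null(istate)) istate <- 2L
  if (istate < 0 || nrow(sol) < length(tt))
    .stopf("ODE integration failed (istate %d) after t = %g s",
           istate, sol[nrow(sol), 1L], class = "photokin_solver")
  if (prepend) sol <- sol[-1L, , drop = FALSE]
  traj <- data.frame(time = sol[, 1L], conc_A = sol[, 2L],
                     conc_B = sol[, 3L])
  out <- list(trajectory = traj)
  if (!is.null(wavelengths)) {
    eA <- interpolate_spectrum(system$eps_A, wavelengths)
    eB <- interpolate_spectrum(system$eps_B, wavelengths)
    out$absorbance <- (outer(traj$conc_A, eA) + outer(traj$conc_B, eB)) *
      geometry$path_probe
    dimnames(out$absorbance) <- list(NULL, sprintf("%g", wavelengths))
    out$wavelengths <- wavelengths
  }
  out
}

#' Model absorbance time series on the probe path
#'
#' Convenience wrapper around [simulate_kinetics()] returning a
#' `photokin_sts` of model spectra on a wavelength grid, in the same
#' container the file readers produce.
#'
#' @inheritParams simulate_kinetics
#' @param wavelengths Wavelength grid (nm) for the model spectra.
#' @return A `photokin_sts`.
#' @export
simulate_spectra <- function(system, phis, source, geometry, initial,
                             times, wavelengths, thermal = TRUE,
                             rtol = 1e-8, atol = 1e-12) {
  sim <- simulate_kinetics(system, phis, source, geometry, initial, times,
                           wavelengths = wavelengths, thermal = thermal,
                           rtol = rtol, atol = atol)
  spectra <- lapply(seq_along(times), function(i)
    spectrum_new(wavelengths, sim$absorbance[i, ], "absorbance",
                 sprintf("t%g", times[i])))
  time_series_new(times, spectra)
}

#' Photostationary-state composition
#'
#' Solves `dA/dt = 0` at fixed total concentration by root bracketing on
#' the mole fraction of B. For monochromatic light with `k_BA = 0` the
#' result matches the closed form `[B]/[A] = (Phi_AB eps_A)/(Phi_BA eps_B)`.
#'
#' @inheritParams rate_monochromatic
#' @param total_conc Total concentration `[A] + [B]` in M.
#' @return Named numeric `c(fraction_A, fraction_B)`.
#' @export
photostationary_state <- function(system, phis, source, geometry,
                                  total_conc = 1e-5, thermal = TRUE) {
  ctx <- .rate_context(system, source, geometry, thermal)
  g <- function(fB) .rate_dA((1 - fB) * total_conc, fB * total_conc,
                             phis, ctx)
  g0 <- g(0); g1 <- g(1)
  if (g0 == 0 && g1 == 0)
    .stopf("rates vanish identically; no unique stationary composition",
           class = "photokin_degenerate")
  if (g0 >= 0 && g1 <= 0)
    .stopf("no stationary point bracketed in (0, 1)", class = "photokin_degenerate")
  if (g0 == 0) return(c(fraction_A = 1, fraction_B = 0))
  if (g1 == 0) return(c(fraction_A = 0, fraction_B = 1))
  fB <- stats::uniroot(g, c(0, 1), tol = 1e-14)$root
  c(fraction_A = 1 - fB, fraction_B = fB)
}

#' Convert wall-clock timestamps to cumulative irradiation time
#'
#' The rate equations assume continuous illumination, but in-operando
#' acquisition switches the LED off for the duration of each spectrum.
#' Given wall-clock sample times and the per-acquisition dead time, this
#' subtracts the accumulated dead time (one acquisition before every
#' sample after the first).
#'
#' @param times Wall-clock times in s, strictly increasing.
#' @param dead_time LED-off seconds per spectrum acquisition.
#' @return Cumulative LED-on times, same length.
#' @export
correct_duty_cycle <- function(times, dead_time) {
  stopifnot(dead_time >= 0, all(diff(times) > 0))
  eff <- times - (seq_along(times) - 1L) * dead_time
  if (any(diff(eff) <= 0))
    .stopf("dead_time %g s exceeds the sampling interval", dead_time,
           class = "photokin_invalid")
  eff
}
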