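# Inverse problem: recover (Phi_AB, Phi_BA) from an absorbance-vs-time
# trace by bounded Levenberg-Marquardt least squares on the photokinetic
# model, then widen the fit standard errors by min/max-power refits.

#' Fit the quantum-yield pair to measured absorbance kinetics
#'
#' Minimizes the residual sum of squares between measured absorbance and
#' the model absorbance obtained by integrating the rate equations, over
#' `Phi_A->B` and `Phi_B->A` bounded to `[0, 1]`, with Levenberg-Marquardt
#' damping (minpack). By default the fit uses the absorbance at the
#' irradiation wavelength (the emission peak for an LED source); several
#' observation wavelengths may be fitted jointly. Standard errors come
#' from the linearized covariance `(J'J)^-1 s^2` at the optimum.
#'
#' @param times Observation times in s (cumulative LED-on time), >= 5
#'   points, strictly increasing.
#' @param absorbance Measured absorbance: a vector (one observation
#'   wavelength) or a matrix with one column per wavelength.
#' @param system A `photokin_system`.
#' @param source A `photokin_source`.
#' @param geometry A `photokin_geometry`.
#' @param initial A `photokin_state`; default 100% A at the total
#'   concentration inferred from the first spectrum is the caller's
#'   responsibility (see [initial_state_from_absorbance()]).
#' @param obs_wavelengths Observation wavelength(s) in nm; default the
#'   source wavelength (monochromatic) or its emission peak.
#' @param init Starting values `c(phi_AB, phi_BA)`, default `c(0.3, 0.3)`.
#' @param lower,upper Box bounds on the yields, default `[0, 1]`.
#' @param weights Optional per-point residual weights (1/sigma), recycled
#'   across wavelengths.
#' @param thermal Include the thermal back-reaction (default `TRUE`).
#' @param fit_initial_fraction If `TRUE`, the initial mole fraction of B
#'   is fitted as a third parameter (samples not fully thermally relaxed).
#' @param dead_time Per-acquisition LED-off time in s subtracted from the
#'   wall-clock timestamps via [correct_duty_cycle()]; default 0 (times
#'   already on the LED-on clock).
#' @param rtol,atol Solver tolerances passed to [simulate_kinetics()].
#' @return A `photokin_qyfit` with fields `phi_AB`, `phi_BA`, `se_AB`,
#'   `se_BA`, `rss`, `n_points`, `converged`, `warnings`, and (after
#'   [propagate_power_uncertainty()]) `phi_min`, `phi_max`, `delta_phi`.
#' @export
fit_quantum_yields <- function(times, absorbance, system, source, geometry,
                               initial, obs_wavelengths = NULL,
                               init = c(0.3, 0.3), lower = c(0, 0),
                               upper = c(1, 1), weights = NULL,
                               thermal = TRUE,
                               fit_initial_fraction = FALSE,
                               dead_time = 0, rtol = 1e-8, atol = 1e-12) {
  times <- as.numeric(times)
  if (dead_time > 0) times <- correct_duty_cycle(times, dead_time)
  A <- as.matrix(absorbance)
  if (length(times) < 5L)
    .stopf("need >= 5 time points, got %d", length(times),
           class = "photokin_invalid")
  if (nrow(A) != length(times))
    .stopf("absorbance rows (%d) must match times (%d)", nrow(A),
           length(times), class = "photokin_invalid")
  if (is.null(obs_wavelengths))
    obs_wavelengths <- if (source$mode == "monochromatic") source$wavelength
                       else source$f$wavelength[which.max(source$f$value)]
  if (ncol(A) != length(obs_wavelengths))
    .stopf("absorbance columns (%d) must match obs_wavelengths (%d)",
           ncol(A), length(obs_wavelengths), class = "photokin_invalid")
  if (!is.null(weights)) weights <- rep_len(weights, length(A))

  warnings <- character()
  if (source$q0 == 0)
    warnings <- c(warnings,
                  "photon flux is zero: quantum yields are unconstrained by the data")
  lam_exc <- if (source$mode == "monochromatic") source$wavelength
             else source$f$wavelength[which.max(source$f$value)]
  if (interpolate_spectrum(system$eps_B, lam_exc) == 0)
    warnings <- c(warnings,
                  "eps_B = 0 at the excitation wavelength: Phi_B->A is weakly identified")
  if (interpolate_spectrum(system$eps_A, lam_exc) == 0)
    warnings <- c(warnings,
                  "eps_A = 0 at the excitation wavelength: Phi_A->B is weakly identified")

  total0 <- initial$conc_A + initial$conc_B
  model_abs <- function(par) {
    phis <- quantum_yields(min(1, max(0, par[1L])),
                           min(1, max(0, par[2L])))
    st <- if (fit_initial_fraction) {
      fB0 <- min(1, max(0, par[3L]))
      kinetic_state((1 - fB0) * total0, fB0 * total0, initial$time)
    } else initial
    sim <- simulate_kinetics(system, phis, source, geometry, st, times,
                             wavelengths = obs_wavelengths,
                             thermal = thermal, rtol = rtol, atol = atol)
    sim$absorbance
  }
  par0 <- if (fit_initial_fraction) c(init, initial$conc_B / total0)
          else init
  lo <- if (fit_initial_fraction) c(lower, 0) else lower
  hi <- if (fit_initial_fraction) c(upper, 1) else upper
  # Box bounds are enforced through the smooth sine reparametrization
  # par = lo + (hi - lo) (sin(theta) + 1) / 2, the standard device for
  # bounded MINPACK Levenberg-Marquardt: the optimum stays interior in
  # theta, so the solver never stalls on a clamped boundary.
  eps_b <- 1e-6 * (hi - lo)
  par0c <- pmin(hi - eps_b, pmax(lo + eps_b, par0))
  to_theta <- function(p) asin(2 * (p - lo) / (hi - lo) - 1)
  to_par <- function(th) lo + (hi - lo) * (sin(th) + 1) / 2
  resid_fn <- function(th) {
    r <- as.numeric(model_abs(to_par(th)) - A)
    if (!is.null(weights)) r <- r * weights
    r
  }
  fit <- minpack.lm::nls.lm(par = to_theta(par0c), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-14, ptol = 1e-14))
  converged <- fit$info %in% 1:4
  if (!converged)
    warnings <- c(warnings, sprintf(
      "optimizer did not report convergence (info %d: %s)", fit$info,
      fit$message))
  par_hat <- to_par(fit$par)
  dpar_dth <- (hi - lo) * cos(fit$par) / 2
  n <- length(A)
  p <- length(par0)
  se <- rep(NA_real_, p)
  if (n > p) {
    resvar <- fit$deviance / (n - p)
    cov_th <- tryCatch(chol2inv(chol(fit$hessian)), error = function(e) NULL)
    if (is.null(cov_th)) {
      warnings <- c(warnings,
                    "singular Jacobian at the optimum: standard errors unavailable (flat likelihood in at least one yield)")
    } else {
      se <- sqrt(pmax(0, diag(cov_th)) * resvar) * abs(dpar_dth)
      se[abs(dpar_dth) < 1e-8] <- NA_real_  # optimum pinned at a bound
      if (anyNA(se))
        warnings <- c(warnings,
                      "optimum at a parameter bound: standard error undefined there")
    }
  }
  structure(list(
    phi_AB = par_hat[1L], phi_BA = par_hat[2L],
    se_AB = se[1L], se_BA = se[2L],
    initial_fraction_B = if (fit_initial_fraction) par_hat[3L] else
      initial$conc_B / total0,
    rss = fit$deviance, n_points = n, converged = converged,
    warnings = warnings,
    phi_min = c(AB = NA_real_, BA = NA_real_),
    phi_max = c(AB = NA_real_, BA = NA_real_),
    delta_phi = c(AB = NA_real_, BA = NA_real_),
    context = list(times = times, absorbance = A, system = system,
                   source = source, geometry = geometry, initial = initial,
                   obs_wavelengths = obs_wavelengths, weights = weights,
                   thermal = thermal,
                   fit_initial_fraction = fit_initial_fraction,
                   lower = lower, upper = upper, rtol = rtol, atol = atol)),
    class = "photokin_qyfit")
}

#' @export
print.photokin_qyfit <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf("<quantum-yield fit (%d points, RSS %.3g%s)>\n", x$n_points,
              x$rss, if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  Phi_A->B = %s +/- %s (fit SE)", fmt(x$phi_AB),
              fmt(x$se_AB)))
  if (!is.na(x$delta_phi["AB"]))
    cat(sprintf("; total Delta = %s [%s, %s]", fmt(x$delta_phi["AB"]),
                fmt(x$phi_min["AB"]), fmt(x$phi_max["AB"])))
  cat("\n")
  cat(sprintf("  Phi_B->A = %s +/- %s (fit SE)", fmt(x$phi_BA),
              fmt(x$se_BA)))
  if (!is.na(x$delta_phi["BA"]))
    cat(sprintf("; total Delta = %s [%s, %s]", fmt(x$delta_phi["BA"]),
                fmt(x$phi_min["BA"]), fmt(x$phi_max["BA"])))
  cat("\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Infer the initial state from the first measured spectrum
#'
#' Assumes a thermally relaxed sample (100% A) and reads the total
#' concentration off the first spectrum at a reference wavelength via
#' Beer-Lambert on the probe path.
#'
#' @param sts A `photokin_sts`.
#' @param system A `photokin_system`.
#' @param geometry A `photokin_geometry`.
#' @param wavelength Reference wavelength in nm; default the maximum of
#'   `eps_A` within the spectral grid.
#' @return A `photokin_state` with `conc_B = 0`.
#' @export
initial_state_from_absorbance <- function(sts, system, geometry,
                                          wavelength = NULL) {
  stopifnot(inherits(sts, "photokin_sts"))
  if (is.null(wavelength)) {
    rng <- range(sts$wavelength)
    in_rng <- system$eps_A$wavelength >= rng[1L] &
      system$eps_A$wavelength <= rng[2L]
    wavelength <- system$eps_A$wavelength[in_rng][
      which.max(system$eps_A$value[in_rng])]
  }
  eA <- interpolate_spectrum(system$eps_A, wavelength)
  if (eA <= 0)
    .stopf("eps_A = 0 at %g nm; cannot infer concentration", wavelength,
           class = "photokin_degenerate")
  a0 <- absorbance_trace(sts, wavelength)$absorbance[1L]
  kinetic_state(a0 / (eA * geometry$path_probe), 0, sts$times[1L])
}

#' Propagate the LED-power uncertainty into the quantum yields
#'
#' Refits the yields with the photon flux rebuilt from the lower and upper
#' power limits `P -/+ multiple * dP`. Writing `Phi_min power` and
#' `Phi_max power` for the smaller and larger refit value of each yield,
#' the total bounds widen by the refits' own fit standard errors,
#' `Phi_min = Phi_min power - dPhi_min power` and
#' `Phi_max = Phi_max power + dPhi_max power`, and the total uncertainty
#' per yield is `max(|Phi - Phi_min|, |Phi - Phi_max|)`.
#'
#' @param fit A `photokin_qyfit` from [fit_quantum_yields()].
#' @param power The pooled `photokin_power_result` behind the photon flux;
#'   alternatively give `rel_uncertainty` directly.
#' @param rel_uncertainty Relative power uncertainty `dP/P`; defaults to
#'   the value carried by the fit's source, or computed from `power`.
#' @param multiple How many reported uncertainties to span; default 1.
#' @return The fit with `phi_min`, `phi_max`, `delta_phi` filled in.
#' @export
propagate_power_uncertainty <- function(fit, power = NULL,
                                        rel_uncertainty = NULL,
                                        multiple = 1) {
  stopifnot(inherits(fit, "photokin_qyfit"))
  ctx <- fit$context
  if (is.null(rel_uncertainty)) {
    rel_uncertainty <- if (!is.null(power)) {
      stopifnot(inherits(power, "photokin_power_result"))
      if (power$mean_power <= 0)
        .stopf("pooled power must be positive", class = "photokin_invalid")
      power$std_power / power$mean_power
    } else {
      ru <- attr(ctx$source, "rel_uncertainty")
      if (is.null(ru))
        .stopf("no power uncertainty available; pass `power` or `rel_uncertainty`",
               class = "photokin_invalid")
      ru
    }
  }
  rel <- multiple * rel_uncertainty
  if (rel < 0 || rel >= 1)
    .stopf("relative power uncertainty must lie in [0, 1), got %g", rel,
           class = "photokin_invalid")
  refit <- function(factor, which_bound) {
    r <- tryCatch(
      fit_quantum_yields(ctx$times, ctx$absorbance, ctx$system,
                         scale_source(ctx$source, factor), ctx$geometry,
                         ctx$initial,
                         obs_wavelengths = ctx$obs_wavelengths,
                         init = c(fit$phi_AB, fit$phi_BA),
                         lower = ctx$lower, upper = ctx$upper,
                         weights = ctx$weights, thermal = ctx$thermal,
                         fit_initial_fraction = ctx$fit_initial_fraction,
                         rtol = ctx$rtol, atol = ctx$atol),
      error = function(e)
        .stopf("refit at the %s-power bound failed: %s", which_bound,
               conditionMessage(e), class = "photokin_refit"))
    if (!r$converged)
      .stopf("refit at the %s-power bound did not converge", which_bound,
             class = "photokin_refit")
    r
  }
  if (rel == 0) {
    lo_fit <- hi_fit <- fit
  } else {
    lo_fit <- refit(1 - rel, "lower")
    hi_fit <- refit(1 + rel, "upper")
  }
  se0 <- function(v) ifelse(is.na(v), 0, v)
  for (nm in c("AB", "BA")) {
    phi <- fit[[paste0("phi_", nm)]]
    cand <- c(lo_fit[[paste0("phi_", nm)]], hi_fit[[paste0("phi_", nm)]])
    cand_se <- se0(c(lo_fit[[paste0("se_", nm)]],
                     hi_fit[[paste0("se_", nm)]]))
    i_min <- which.min(cand); i_max <- which.max(cand)
    pmin_ <- cand[i_min] - cand_se[i_min]
    pmax_ <- cand[i_max] + cand_se[i_max]
    # the widened interval must cover the central estimate
    pmin_ <- min(pmin_, phi)
    pmax_ <- max(pmax_, phi)
    fit$phi_min[nm] <- pmin_
    fit$phi_max[nm] <- pmax_
    fit$delta_phi[nm] <- max(abs(phi - pmin_), abs(phi - pmax_))
  }
  fit
}

#' Aggregate replicate quantum-yield determinations
#'
#' Inverse-variance weighted mean over replicates with weights
#' `w_i = 1 / delta_phi_i^2`, and the weighted sample standard deviation
#' `sqrt(sum(w (phi - mean)^2) / (((n-1)/n) sum(w)))` for `n >= 2`. A
#' single replicate is passed through with its own `delta_phi`.
#'
#' @param phi Numeric vector of replicate yields.
#' @param delta_phi Matching vector of total per-replicate uncertainties,
#'   all > 0 when `n >= 2`.
#' @return List with `phi_weighted_mean`, `sample_std` (`NA` for a single
#'   replicate), `delta_phi_single` (only for `n = 1`), `n_replicates`.
#' @export
aggregate_replicates <- function(phi, delta_phi) {
  stopifnot(length(phi) == length(delta_phi), length(phi) >= 1L)
  n <- length(phi)
  if (n == 1L) {
    if (delta_phi <= 0)
      .stopf("single replicate needs delta_phi > 0", class = "photokin_invalid")
    return(list(phi_weighted_mean = phi, sample_std = NA_real_,
                delta_phi_single = delta_phi, n_replicates = 1L))
  }
  if (any(delta_phi <= 0))
    .stopf("replicate %d has delta_phi <= 0; supply explicit nonzero uncertainties",
           which(delta_phi <= 0)[1L], class = "photokin_ambiguous")
  w <- 1 / delta_phi^2
  m <- sum(w * phi) / sum(w)
  s <- sqrt(sum(w * (phi - m)^2) / (((n - 1) / n) * sum(w)))
  list(phi_weighted_mean = m, sample_std = s, n_replicates = n)
}

#' Serialize a quantum-yield fit as key-value text
#'
#' @param fit A `photokin_qyfit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "photokin_qyfit"))
  kv <- c(phi_AB = fit$phi_AB, se_AB = fit$se_AB,
          phi_AB_min = unname(fit$phi_min["AB"]),
          phi_AB_max = unname(fit$phi_max["AB"]),
          delta_phi_AB = unname(fit$delta_phi["AB"]),
          phi_BA = fit$phi_BA, se_BA = fit$se_BA,
          phi_BA_min = unname(fit$phi_min["BA"]),
          phi_BA_max = unname(fit$phi_max["BA"]),
          delta_phi_BA = unname(fit$delta_phi["BA"]),
          rss = fit$rss, n_points = fit$n_points)
  lines <- c(sprintf("%s=%.10g", names(kv), kv),
             sprintf("converged=%s", tolower(as.character(fit$converged))))
  if (length(fit$warnings))
    lines <- c(lines, sprintf("warning=%s", fit$warnings))
  writeLines(lines, path)
  invisible(path)
}
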