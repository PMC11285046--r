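# Shared fixtures: the azobenzene-like toy switch irradiated at 340 nm
# under conditions mirroring a typical determination (3.00 mL, 1 cm paths,
# 1 h at one spectrum per 30 s, ~1 mW LED, initial absorbance 0.9).

toy_setup <- function(p_true = 1e-3, lambda = 340, k_BA = 7.2e-7,
                      duration = 3600, interval = 30) {
  system <- make_toy_switch(k_BA = k_BA)
  geometry <- experiment_geometry()
  source <- photon_flux(power_result_new(p_true, 0), wavelength = lambda)
  conc <- 0.9 / (interpolate_spectrum(system$eps_A, lambda) *
                   geometry$path_probe)
  list(system = system, geometry = geometry, source = source,
       initial = kinetic_state(conc, 0), conc = conc, lambda = lambda,
       times = irradiation_schedule(duration, interval))
}

# flat toy spectra over a short range; handy for closed-form checks
flat_system <- function(eA = 1000, eB = 500, k_BA = 0,
                        grid = seq(300, 400, by = 10)) {
  photoswitch_system(
    spectrum_new(grid, rep(eA, length(grid)), "M-1cm-1"),
    spectrum_new(grid, rep(eB, length(grid)), "M-1cm-1"),
    k_BA)
}

# independent fixed-step classical Runge-Kutta integrator over the same
# rate law, written as a plain transcription (oracle for the adaptive
# solver)
rk4_integrate <- function(rate_dA, y0, t_out, h) {
  f <- function(y) { d <- rate_dA(y[1L], y[2L]); c(d, -d) }
  y <- y0
  t <- t_out[1L]
  out <- matrix(NA_real_, length(t_out), 2L)
  out[1L, ] <- y0
  for (i in seq_along(t_out)[-1L]) {
    while (t < t_out[i] - 1e-12) {
      step <- min(h, t_out[i] - t)
      k1 <- f(y)
      k2 <- f(y + step / 2 * k1)
      k3 <- f(y + step / 2 * k2)
      k4 <- f(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  out
}

# direct transcription of the two-state rate law built stepwise from the
# photon-uptake bookkeeping: q_X = q0 * share_X * absorbed_fraction, then
# dA/dt = -Phi_AB q_A/(N_A V) + Phi_BA q_B/(N_A V) + k_BA [B]
stepwise_rate_dA <- function(cA, cB, eA, eB, l, q0, V, phi_AB, phi_BA,
                             k_BA) {
  NA_ <- 6.02214076e23
  abs_A <- cA * eA * l
  abs_B <- cB * eB * l
  abs_tot <- abs_A + abs_B
  P <- 1 - 10^(-abs_tot)
  if (abs_tot == 0) return(k_BA * cB)
  q_A <- q0 * (abs_A / abs_tot) * P
  q_B <- q0 * (abs_B / abs_tot) * P
  -phi_AB * q_A / (NA_ * V) + phi_BA * q_B / (NA_ * V) + k_BA * cB
}
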