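test_that("absorbed fraction follows 1 - 10^-Abs", {
  expect_equal(absorbed_fraction(0), 0)
  expect_equal(absorbed_fraction(1), 0.9)
  expect_equal(absorbed_fraction(2), 0.99)
  expect_error(absorbed_fraction(-0.1), class = "photokin_invalid")
})

test_that("species photon shares partition by absorbance ratio", {
  expect_equal(unname(species_photon_share(0.3, 0)), c(1, 0))
  expect_equal(unname(species_photon_share(0.4, 0.4)), c(0.5, 0.5))
  expect_equal(unname(species_photon_share(0.8, 0.2)), c(0.8, 0.2))
  expect_error(species_photon_share(0, 0), class = "photokin_degenerate")
  # photon bookkeeping: q_A + q_B = q0 * absorbed_fraction
  for (ab in list(c(0.8, 0.2), c(0.05, 0.55), c(1.2, 0.9))) {
    sh <- species_photon_share(ab[1], ab[2])
    P <- absorbed_fraction(sum(ab))
    q0 <- 1.7e15
    expect_equal(q0 * sh[["share_A"]] * P + q0 * sh[["share_B"]] * P,
                 q0 * P, tolerance = 1e-14)
  }
})

test_that("the inner-filter factor is continuous down to zero absorbance", {
  f <- photokin:::.inner_filter_factor
  expect_equal(f(0), log(10))
  for (x in 10^seq(-14, -6)) {
    expect_lt(abs(f(x) - log(10)) / log(10), 1e-5)
  }
  # relative jump across the analytic switch at 0 is below 1e-10
  expect_lt(abs(f(1e-13) - f(0)) / f(0), 1e-10)
  expect_equal(f(1), 0.9 / 1)
})

test_that("monochromatic rates: dark limits and the thermal term", {
  setup <- toy_setup()
  dark <- monochromatic_source(0, 340)
  sys0 <- make_toy_switch(k_BA = 0)
  st <- kinetic_state(1e-5, 0)
  r <- rate_monochromatic(st, sys0, quantum_yields(0.2, 0.4), dark,
                          setup$geometry)
  expect_identical(unname(r), c(0, 0))

  # thermal-only: dA/dt = k_BA [B] with the azobenzene rate constant
  st2 <- kinetic_state(0, 1e-5)
  r2 <- rate_monochromatic(st2, make_toy_switch(k_BA = 7.2e-7),
                           quantum_yields(0.2, 0.4), dark, setup$geometry)
  expect_equal(r2[["dA_dt"]], 7.2e-12, tolerance = 1e-12)
  expect_equal(r2[["dB_dt"]], -7.2e-12, tolerance = 1e-12)
})

test_that("the combined rate law equals the stepwise photon-bookkeeping composition", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  eA <- interpolate_spectrum(setup$system$eps_A, 340)
  eB <- interpolate_spectrum(setup$system$eps_B, 340)
  states <- list(c(5e-5, 0), c(3e-5, 2e-5), c(1e-6, 4.9e-5), c(0, 5e-5))
  for (cc in states) {
    r <- rate_monochromatic(kinetic_state(cc[1], cc[2]), setup$system,
                            phis, setup$source, setup$geometry)
    oracle <- stepwise_rate_dA(cc[1], cc[2], eA, eB,
                               setup$geometry$path_irradiation,
                               setup$source$q0, setup$geometry$volume,
                               phis$phi_AB, phis$phi_BA,
                               setup$system$k_BA)
    expect_equal(r[["dA_dt"]], oracle, tolerance = 1e-14)
    expect_identical(r[["dB_dt"]], -r[["dA_dt"]])  # exact antisymmetry
  }
})

test_that("single-bin emission reproduces the monochromatic rate", {
  setup <- toy_setup()
  spike <- make_led_profile(340, fwhm = 0.5)
  src_poly <- photon_flux(power_result_new(1e-3, 0), emission = spike)
  phis <- quantum_yields(0.16, 0.38)
  st <- kinetic_state(3e-5, 2e-5)
  r_mono <- rate_monochromatic(st, setup$system, phis, setup$source,
                               setup$geometry)
  r_poly <- rate_polychromatic(st, setup$system, phis, src_poly,
                               setup$geometry)
  expect_equal(r_poly[["dA_dt"]], r_mono[["dA_dt"]], tolerance = 1e-6)
  expect_identical(r_poly[["dB_dt"]], -r_poly[["dA_dt"]])

  # empty cuvette: no photochemistry, no thermal flux
  r0 <- rate_polychromatic(kinetic_state(0, 0), setup$system, phis,
                           src_poly, setup$geometry)
  expect_identical(unname(r0), c(0, 0))
})

test_that("emission quadrature is converged on the native grid", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  st <- kinetic_state(3e-5, 2e-5)
  led_coarse <- make_led_profile(340, fwhm = 12, step = 1)
  led_fine <- make_led_profile(340, fwhm = 12, step = 0.5)
  r1 <- rate_polychromatic(st, setup$system, phis,
                           photon_flux(power_result_new(1e-3, 0),
                                       emission = led_coarse),
                           setup$geometry)
  r2 <- rate_polychromatic(st, setup$system, phis,
                           photon_flux(power_result_new(1e-3, 0),
                                       emission = led_fine),
                           setup$geometry)
  expect_equal(r1[["dA_dt"]], r2[["dA_dt"]], tolerance = 1e-4)
})

test_that("dark thermal decay integrates to the closed-form exponential", {
  k <- 2e-4
  sys <- make_toy_switch(k_BA = k)
  setup <- toy_setup()
  dark <- monochromatic_source(0, 340)
  b0 <- 5e-5
  tt <- seq(0, 2 / k, length.out = 40)
  sim <- simulate_kinetics(sys, quantum_yields(0.2, 0.4), dark,
                           setup$geometry, kinetic_state(0, b0), tt)
  expect_equal(sim$trajectory$conc_B, b0 * exp(-k * tt), tolerance = 1e-6)
})

test_that("total concentration is conserved along photochemical trajectories", {
  setup <- toy_setup()
  sim <- simulate_kinetics(setup$system, quantum_yields(0.16, 0.38),
                           setup$source, setup$geometry, setup$initial,
                           setup$times)
  total <- sim$trajectory$conc_A + sim$trajectory$conc_B
  expect_lt(max(abs(total - setup$conc)), 1e-10 * setup$conc)
  expect_true(all(sim$trajectory$conc_A >= -1e-15))
})

test_that("the adaptive solver matches an independent fixed-step Runge-Kutta", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  tt <- seq(0, 600, by = 60)
  sim <- simulate_kinetics(setup$system, phis, setup$source,
                           setup$geometry, setup$initial, tt)
  eA <- interpolate_spectrum(setup$system$eps_A, 340)
  eB <- interpolate_spectrum(setup$system$eps_B, 340)
  rate <- function(cA, cB)
    stepwise_rate_dA(cA, cB, eA, eB, setup$geometry$path_irradiation,
                     setup$source$q0, setup$geometry$volume,
                     phis$phi_AB, phis$phi_BA, setup$system$k_BA)
  oracle <- rk4_integrate(rate, c(setup$conc, 0), tt, h = 0.5)
  expect_equal(sim$trajectory$conc_A, oracle[, 1L], tolerance = 1e-6)
  expect_equal(sim$trajectory$conc_B, oracle[, 2L], tolerance = 1e-6)
})

test_that("trajectories are invariant under refinement of the output grid", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  coarse <- seq(0, 1800, by = 300)
  fine <- seq(0, 1800, by = 30)
  # run below the default solver tolerance so the comparison probes the
  # output-grid dependence, not the integration error itself
  s1 <- simulate_kinetics(setup$system, phis, setup$source,
                          setup$geometry, setup$initial, coarse,
                          rtol = 1e-10, atol = 1e-14)
  s2 <- simulate_kinetics(setup$system, phis, setup$source,
                          setup$geometry, setup$initial, fine,
                          rtol = 1e-10, atol = 1e-14)
  keep <- fine %in% coarse
  expect_lt(max(abs(s2$trajectory$conc_A[keep] - s1$trajectory$conc_A)),
            1e-8 * setup$conc)
})

test_that("the approach to the photostationary state is monotone", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  pss <- photostationary_state(setup$system, phis, setup$source,
                               setup$geometry, total_conc = setup$conc)
  sim <- simulate_kinetics(setup$system, phis, setup$source,
                           setup$geometry, setup$initial, setup$times)
  gap <- abs(sim$trajectory$conc_A - pss[["fraction_A"]] * setup$conc)
  expect_true(all(diff(gap) <= 1e-12 * setup$conc))
})

test_that("photostationary state matches the closed form and its limits", {
  geo <- experiment_geometry()
  # symmetric: k=0 and Phi_AB eps_A = Phi_BA eps_B -> 50/50
  sys <- flat_system(eA = 1000, eB = 500, k_BA = 0)
  src <- monochromatic_source(1e15, 350)
  pss <- photostationary_state(sys, quantum_yields(0.2, 0.4), src, geo)
  expect_equal(unname(pss), c(0.5, 0.5), tolerance = 1e-10)

  # general closed form [B]/[A] = Phi_AB eps_A / (Phi_BA eps_B) at k = 0
  sys2 <- make_toy_switch(k_BA = 0)
  phis <- quantum_yields(0.16, 0.38)
  pss2 <- photostationary_state(sys2, phis, monochromatic_source(1e15, 340),
                                geo, total_conc = 5e-5)
  eA <- interpolate_spectrum(sys2$eps_A, 340)
  eB <- interpolate_spectrum(sys2$eps_B, 340)
  ratio <- phis$phi_AB * eA / (phis$phi_BA * eB)
  expect_equal(pss2[["fraction_B"]] / pss2[["fraction_A"]], ratio,
               tolerance = 1e-10)

  # thermal-only equilibrium is all-A
  sys3 <- make_toy_switch(k_BA = 7.2e-7)
  pss3 <- photostationary_state(sys3, phis, monochromatic_source(0, 340),
                                geo)
  expect_equal(pss3[["fraction_A"]], 1)
})

test_that("duty-cycle correction subtracts accumulated acquisition dead time", {
  tt <- seq(0, 300, by = 30)
  eff <- correct_duty_cycle(tt, dead_time = 0.5)
  expect_equal(eff, tt - (seq_along(tt) - 1) * 0.5)
  expect_error(correct_duty_cycle(tt, dead_time = 31),
               class = "photokin_invalid")
})
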