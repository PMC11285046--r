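test_that("noiseless data return the generating quantum yields", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  sim <- simulate_kinetics(setup$system, phis, setup$source,
                           setup$geometry, setup$initial, setup$times,
                           wavelengths = 340)
  fit <- fit_quantum_yields(setup$times, sim$absorbance[, 1], setup$system,
                            setup$source, setup$geometry, setup$initial)
  expect_true(fit$converged)
  expect_lt(abs(fit$phi_AB - 0.16) / 0.16, 1e-4)
  expect_lt(abs(fit$phi_BA - 0.38) / 0.38, 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("noiseless recovery holds across the feasible quantum-yield square", {
  # property sweep on a shortened schedule (20 min at 60 s sampling)
  setup <- toy_setup(duration = 1200, interval = 60)
  pairs <- list(c(0.02, 0.5), c(0.3, 0.02), c(0.5, 0.98), c(0.98, 0.6),
                c(0.16, 0.38))
  for (p in pairs) {
    phis <- quantum_yields(p[1], p[2])
    sim <- simulate_kinetics(setup$system, phis, setup$source,
                             setup$geometry, setup$initial, setup$times,
                             wavelengths = 340)
    fit <- fit_quantum_yields(setup$times, sim$absorbance[, 1],
                              setup$system, setup$source, setup$geometry,
                              setup$initial)
    expect_lt(abs(fit$phi_AB - p[1]) / p[1], 1e-3)
    expect_lt(abs(fit$phi_BA - p[2]) / p[2], 1e-3)
  }
})

test_that("under noise the truth lies within three standard errors", {
  setup <- toy_setup()
  phis <- quantum_yields(0.16, 0.38)
  e <- simulate_noisy_experiment(setup$system, phis, setup$source,
                                 setup$geometry, setup$initial,
                                 setup$times, noise_sd = 0.002, seed = 21)
  obs <- absorbance_trace(e$sts, 340)$absorbance
  fit <- fit_quantum_yields(setup$times, obs, setup$system, setup$source,
                            setup$geometry, setup$initial)
  expect_lt(abs(fit$phi_AB - 0.16), 3 * fit$se_AB)
  expect_lt(abs(fit$phi_BA - 0.38), 3 * fit$se_BA)
})

test_that("zero photon flux yields an identifiability warning, not a silent fit", {
  setup <- toy_setup()
  dark <- monochromatic_source(0, 340)
  tt <- seq(0, 300, by = 60)
  sim <- simulate_kinetics(setup$system, quantum_yields(0.2, 0.4), dark,
                           setup$geometry, setup$initial, tt,
                           wavelengths = 340)
  fit <- fit_quantum_yields(tt, sim$absorbance[, 1], setup$system, dark,
                            setup$geometry, setup$initial)
  expect_true(any(grepl("unconstrained", fit$warnings)))
})

test_that("the fit is invariant under photon-dose rescaling when k_BA = 0", {
  setup <- toy_setup(k_BA = 0, duration = 1200, interval = 60)
  sys0 <- make_toy_switch(k_BA = 0)
  phis <- quantum_yields(0.25, 0.45)
  sim <- simulate_kinetics(sys0, phis, setup$source, setup$geometry,
                           setup$initial, setup$times, wavelengths = 340)
  fit1 <- fit_quantum_yields(setup$times, sim$absorbance[, 1], sys0,
                             setup$source, setup$geometry, setup$initial)
  # same photon dose: q0 -> 3 q0, t -> t/3
  src3 <- scale_source(setup$source, 3)
  fit2 <- fit_quantum_yields(setup$times / 3, sim$absorbance[, 1], sys0,
                             src3, setup$geometry, setup$initial)
  expect_equal(fit2$phi_AB, fit1$phi_AB, tolerance = 1e-6)
  expect_equal(fit2$phi_BA, fit1$phi_BA, tolerance = 1e-6)
})

test_that("the returned optimum beats random feasible yield pairs", {
  setup <- toy_setup(duration = 1200, interval = 60)
  phis <- quantum_yields(0.16, 0.38)
  e <- simulate_noisy_experiment(setup$system, phis, setup$source,
                                 setup$geometry, setup$initial,
                                 setup$times, noise_sd = 0.002, seed = 8)
  obs <- absorbance_trace(e$sts, 340)$absorbance
  fit <- fit_quantum_yields(setup$times, obs, setup$system, setup$source,
                            setup$geometry, setup$initial)
  rss_at <- function(p) {
    s <- simulate_kinetics(setup$system, quantum_yields(p[1], p[2]),
                           setup$source, setup$geometry, setup$initial,
                           setup$times, wavelengths = 340)
    sum((s$absorbance[, 1] - obs)^2)
  }
  set.seed(123)
  cand <- matrix(runif(200), ncol = 2)
  rss_rand <- apply(cand, 1, rss_at)
  expect_true(all(fit$rss <= rss_rand + 1e-15))
})

test_that("narrow-band LEDs give near-identical single-wavelength and integrated fits", {
  setup <- toy_setup(duration = 1200, interval = 60)
  phis <- quantum_yields(0.16, 0.38)
  led2 <- make_led_profile(340, fwhm = 2)
  src_int <- photon_flux(power_result_new(1e-3, 0), emission = led2)
  sim <- simulate_kinetics(setup$system, phis, src_int, setup$geometry,
                           setup$initial, setup$times, wavelengths = 340)
  fit_int <- fit_quantum_yields(setup$times, sim$absorbance[, 1],
                                setup$system, src_int, setup$geometry,
                                setup$initial, obs_wavelengths = 340)
  fit_mono <- fit_quantum_yields(setup$times, sim$absorbance[, 1],
                                 setup$system, setup$source,
                                 setup$geometry, setup$initial)
  expect_lt(abs(fit_mono$phi_AB - fit_int$phi_AB) / fit_int$phi_AB, 0.005)
  expect_lt(abs(fit_mono$phi_BA - fit_int$phi_BA) / fit_int$phi_BA, 0.005)

  # a broad LED departs further from the monochromatic approximation
  led20 <- make_led_profile(340, fwhm = 25)
  src20 <- photon_flux(power_result_new(1e-3, 0), emission = led20)
  sim20 <- simulate_kinetics(setup$system, phis, src20, setup$geometry,
                             setup$initial, setup$times, wavelengths = 340)
  fit_mono20 <- fit_quantum_yields(setup$times, sim20$absorbance[, 1],
                                   setup$system, setup$source,
                                   setup$geometry, setup$initial)
  expect_gt(abs(fit_mono20$phi_AB - 0.16) / 0.16,
            abs(fit_mono$phi_AB - fit_int$phi_AB) / fit_int$phi_AB)
})

test_that("power-limit propagation widens the yields per the min/max rule", {
  setup <- toy_setup(duration = 1200, interval = 60)
  phis <- quantum_yields(0.16, 0.38)
  sim <- simulate_kinetics(setup$system, phis, setup$source,
                           setup$geometry, setup$initial, setup$times,
                           wavelengths = 340)
  fit <- fit_quantum_yields(setup$times, sim$absorbance[, 1], setup$system,
                            setup$source, setup$geometry, setup$initial)

  # degenerate: no power uncertainty, essentially zero fit SEs
  f0 <- propagate_power_uncertainty(fit, rel_uncertainty = 0)
  expect_equal(unname(f0$phi_min["AB"]), f0$phi_AB, tolerance = 1e-9)
  expect_equal(unname(f0$phi_max["AB"]), f0$phi_AB, tolerance = 1e-9)
  expect_lt(max(f0$delta_phi), 1e-6)

  # 2% power uncertainty on noiseless data: the power error dominates and
  # delta_phi/phi tracks the 2%
  f2 <- propagate_power_uncertainty(fit, rel_uncertainty = 0.02)
  expect_true(f2$phi_min["AB"] <= f2$phi_AB && f2$phi_AB <= f2$phi_max["AB"])
  expect_true(f2$phi_min["BA"] <= f2$phi_BA && f2$phi_BA <= f2$phi_max["BA"])
  expect_equal(unname(f2$delta_phi["AB"]) / f2$phi_AB, 0.02,
               tolerance = 0.25)
  expect_equal(unname(f2$delta_phi["BA"]) / f2$phi_BA, 0.02,
               tolerance = 0.25)
  # yields scale roughly inversely with photon flux near the optimum, so
  # the lower yield bound comes from the higher power
  expect_lt(unname(f2$phi_min["AB"]), fit$phi_AB)
})

test_that("replicate aggregation implements inverse-variance weighting", {
  # identical replicates
  agg <- aggregate_replicates(c(0.3, 0.3, 0.3), c(0.01, 0.01, 0.01))
  expect_equal(agg$phi_weighted_mean, 0.3)
  expect_equal(agg$sample_std, 0)

  # equal uncertainties reduce to the unweighted mean
  agg2 <- aggregate_replicates(c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(agg2$phi_weighted_mean, 0.3)

  # hand-checked weighted case: weights 1e4 and 2.5e3
  agg3 <- aggregate_replicates(c(0.30, 0.36), c(0.01, 0.02))
  expect_equal(agg3$phi_weighted_mean,
               (1e4 * 0.30 + 2.5e3 * 0.36) / (1e4 + 2.5e3))

  # single replicate passes through its own uncertainty
  agg4 <- aggregate_replicates(0.31, 0.02)
  expect_equal(agg4$delta_phi_single, 0.02)

  expect_error(aggregate_replicates(c(0.3, 0.4), c(0.01, 0)),
               class = "photokin_ambiguous")
})

test_that("inverse-variance weighting beats the plain mean under heteroscedastic noise", {
  set.seed(77)
  truth <- 0.35
  sds <- c(0.005, 0.02, 0.05)
  wins <- 0
  n_mc <- 1000
  for (i in seq_len(n_mc)) {
    phi <- truth + rnorm(3, 0, sds)
    agg <- aggregate_replicates(phi, sds)
    if (abs(agg$phi_weighted_mean - truth) <= abs(mean(phi) - truth))
      wins <- wins + 1
  }
  expect_gte(wins / n_mc, 0.8)
})

test_that("fit reports serialize every headline quantity", {
  setup <- toy_setup(duration = 600, interval = 60)
  phis <- quantum_yields(0.16, 0.38)
  sim <- simulate_kinetics(setup$system, phis, setup$source,
                           setup$geometry, setup$initial, setup$times,
                           wavelengths = 340)
  fit <- fit_quantum_yields(setup$times, sim$absorbance[, 1], setup$system,
                            setup$source, setup$geometry, setup$initial)
  fit <- propagate_power_uncertainty(fit, rel_uncertainty = 0.02)
  f <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, f)
  txt <- readLines(f)
  for (key in c("phi_AB=", "se_AB=", "phi_AB_min=", "phi_AB_max=",
                "delta_phi_AB=", "phi_BA=", "rss=", "n_points=",
                "converged="))
    expect_true(any(startsWith(txt, key)), info = key)
})
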