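test_that("reoxidation fitting recovers the decay rate", {
  td <- seq(0, 600, length.out = 10)
  # noiseless radical decay: exact recovery
  conc <- reoxidation_decay(reoxidation_curve_params(0, 1, 0.005), td)
  fit <- fit_reoxidation(conc$td, conc$fadh_rad, "fadh_rad")
  expect_equal(fit$k1b, 0.005, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$half_life, log(2) / fit$k1b)
  # noiseless FADox recovery fit
  conc2 <- reoxidation_decay(reoxidation_curve_params(0.3, 0.7, 0.004), td)
  fit2 <- fit_reoxidation(conc2$td, conc2$fad_ox, "fad_ox")
  expect_equal(fit2$k1b, 0.004, tolerance = 1e-7)
  expect_equal(fit2$c_ox, 0.3, tolerance = 1e-7)
  # constant data means no observable decay
  expect_warning(flat <- fit_reoxidation(td, rep(0.6, 10), "fadh_rad"),
                 "constant")
  expect_equal(flat$k1b, 0)
  expect_error(fit_reoxidation(c(0, 10), c(1, 0.5)), "3 points")
})

test_that("reoxidation fitting tolerates noise (Monte-Carlo recovery)", {
  td <- seq(0, 3 * log(2) / 0.003, length.out = 20)
  true <- reoxidation_decay(reoxidation_curve_params(0, 1, 0.003), td)
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    obs <- true$fadh_rad * (1 + stats::rnorm(20, 0, 0.01))
    abs(fit_reoxidation(td, obs, "fadh_rad")$k1b / 0.003 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("two-state inversion recovers k1", {
  # no conversion observed means no photoreduction
  expect_equal(infer_k1(0, "fadh_rad", t_illum = 20, k1b = 0.01), 0)
  # closed form when reoxidation is neglected
  expect_equal(infer_k1(0.5, "fadh_rad", 20, 0), log(2) / 20,
               tolerance = 1e-12)
  # forward-inverse round trip with reoxidation included, both species
  h <- two_state_concentrations(0.01, 0.003, 20)
  expect_equal(infer_k1(h[["fadh_rad"]], "fadh_rad", 20, 0.003), 0.01,
               tolerance = 1e-8)
  expect_equal(infer_k1(h[["fad_ox"]], "fad_ox", 20, 0.003), 0.01,
               tolerance = 1e-8)
  # round-trip identity over a log grid of rates
  for (k1 in 10^seq(-4, 0, length.out = 9)) {
    obs <- two_state_concentrations(k1, 0.003, 20)[["fadh_rad"]]
    expect_equal(infer_k1(obs, "fadh_rad", 20, 0.003) / k1, 1,
                 tolerance = 1e-8)
  }
  # strictly increasing in the observed concentration
  ks <- vapply(seq(0.05, 0.9, by = 0.05), function(h)
    infer_k1(h, "fadh_rad", 20, 0.003), numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_error(infer_k1(1, "fadh_rad", 20, 0.003), "\\[0, 1\\)")
})

test_that("three-state inversion recovers k2", {
  # observation equal to the zero-green prediction
  h0 <- simulate_photocycle(rate_constants(k1 = 0.016), times = 20)$fadh_rad
  expect_equal(infer_k2(h0, 20, k1 = 0.016), 0)
  # forward-inverse round trip, reoxidation neglected
  h <- simulate_photocycle(rate_constants(0.016, 0.008), times = 20)$fadh_rad
  expect_equal(infer_k2(h, 20, 0.016), 0.008, tolerance = 1e-8)
  # round trip with reoxidation included
  hr <- simulate_photocycle(rate_constants(0.016, 0.008, 0.003, 0.011),
                            times = 20)$fadh_rad
  expect_equal(infer_k2(hr, 20, 0.016, 0.003, 0.011), 0.008,
               tolerance = 1e-8)
  # identity over a log grid
  for (k2 in 10^seq(-4, 0, length.out = 9)) {
    obs <- simulate_photocycle(rate_constants(0.016, k2),
                               times = 20)$fadh_rad
    expect_equal(infer_k2(obs, 20, 0.016) / k2, 1, tolerance = 1e-8)
  }
  # inconsistent observation (more radical than blue light can make)
  expect_error(infer_k2(h0 + 0.05, 20, 0.016), "inconsistent")
})

test_that("neglecting reoxidation at short illumination changes sigma2 < 2%", {
  # Generate a green dose series with full kinetics, then analyze it twice:
  # with the true reoxidation rates, and in the reduced short-illumination
  # framework (k1b = k2b = 0, with k1 consistently re-inferred from the
  # zero-green baseline under the same assumption). The fitted cross
  # sections agree to ~1%, echoing the published comparison.
  cfg <- synthetic_config(noise_sd = 0)
  ser <- generate_green_dose_series(cfg, neglect_reoxidation = FALSE)
  ser <- normalize_to_dark(ser, ser[[1]])
  conc <- series_concentrations(ser[-1], tol = 1e-6)
  k1_true <- cfg$sigma1_true * cfg$blue_co_fluence
  k2_full <- vapply(seq_len(nrow(conc)), function(i)
    infer_k2(conc$fadh_rad[i], cfg$t_illum, k1_true, cfg$k1b_true,
             cfg$k2b_true, tol = 0.05), numeric(1))
  k1_red <- infer_k1(conc$fadh_rad[1], "fadh_rad", cfg$t_illum, 0)
  k2_red <- vapply(seq_len(nrow(conc)), function(i)
    infer_k2(conc$fadh_rad[i], cfg$t_illum, k1_red, 0, 0, tol = 0.05),
    numeric(1))
  s_full <- fit_cross_section(cfg$green_fluences, k2_full)$sigma
  s_red <- fit_cross_section(cfg$green_fluences, k2_red)$sigma
  expect_equal(s_full / cfg$sigma2_true, 1, tolerance = 1e-6)
  expect_lt(abs(s_red / s_full - 1), 0.02)
})

test_that("through-origin dose-response fit estimates the cross section", {
  I <- c(10, 100, 400)
  f <- fit_cross_section(I, 1.6e-4 * I)
  expect_equal(f$sigma, 1.6e-4, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # a single fluence point suffices (R^2 undefined)
  f1 <- fit_cross_section(100, 0.016)
  expect_equal(f1$sigma, 1.6e-4)
  expect_true(is.na(f1$r_squared))
  # Monte-Carlo recovery under 5% noise on the rates
  I6 <- c(25, 50, 100, 200, 400, 800)
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    k <- 2.5e-4 * I6 * (1 + stats::rnorm(6, 0, 0.05))
    abs(fit_cross_section(I6, k)$sigma / 2.5e-4 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_error(fit_cross_section(c(0, 0), c(0, 0)), "zero")
  # inverse-variance weights reweight without changing exact data
  fw <- fit_cross_section(I, 1.6e-4 * I, weights = c(1, 5, 2))
  expect_equal(fw$sigma, 1.6e-4, tolerance = 1e-12)
})

test_that("quantum yield bridges cross section and extinction", {
  expect_equal(round(quantum_yield(1.6e-4, 509.4), 3), 0.137)
  expect_equal(round(quantum_yield(6.4e-5, 641.55), 3), 0.043)
  expect_equal(quantum_yield(0, 509.4), 0)
  # phi -> sigma -> phi is the identity
  for (phi in c(0.01, 0.137, 0.41, 0.9)) {
    sigma <- 2.3 * 509.4 * phi * 1e-6
    expect_equal(quantum_yield(sigma, 509.4), phi, tolerance = 1e-12)
  }
  expect_warning(quantum_yield(1e-2, 509.4), "> 1")
  expect_error(quantum_yield(1e-4, 0), "> 0")
})

test_that("condition summaries average the two species-based analyses", {
  fa <- fit_cross_section(c(100, 200), 1.6e-4 * c(100, 200))
  fb <- fit_cross_section(c(100, 200), 2.8e-4 * c(100, 200))
  ra <- cross_section_result(fa, 509.4)
  rb <- cross_section_result(fb, 509.4, species_fitted = "fad_ox")
  row <- average_condition_summary("Cry2 pH = 7.5", ra, rb)
  expect_equal(round(row$phi, 2), 0.19)
  # mean of the two printed half-lives
  mk_reox <- function(k1b) {
    td <- seq(0, 600, length.out = 8)
    conc <- reoxidation_decay(reoxidation_curve_params(0, 1, k1b), td)
    fit_reoxidation(td, conc$fadh_rad, "fadh_rad")
  }
  row2 <- average_condition_summary("Cry2 pH = 7.5",
                                    mk_reox(log(2) / 231),
                                    mk_reox(log(2) / 192))
  expect_equal(row2$tau_half_s, 211.5, tolerance = 1e-6)
  # averaging identical results is idempotent
  row3 <- average_condition_summary("x", ra, ra)
  expect_equal(row3$phi, ra$phi)
  expect_error(average_condition_summary("x", ra, mk_reox(0.003)),
               "same type")
})

test_that("full in vitro pipeline recovers phi1 under 1% absorbance noise", {
  phi_true <- quantum_yield(1.6e-4, 509.4)
  errs <- vapply(1:100, function(s) {
    cfg <- synthetic_config(noise_sd = 0.01, seed = s)
    k1b_hat <- recover_k1b(cfg)$k1b
    ser <- generate_blue_dose_series(cfg)
    ser <- normalize_to_dark(ser, ser[[1]])
    conc <- series_concentrations(ser[-1], tol = 0.1)
    k1 <- vapply(seq_len(nrow(conc)), function(i)
      infer_k1(min(conc$fadh_rad[i], 1 - 1e-12), "fadh_rad",
               cfg$t_illum, k1b_hat), numeric(1))
    phi <- quantum_yield(fit_cross_section(cfg$blue_fluences, k1)$sigma,
                         509.4)
    abs(phi / phi_true - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})
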