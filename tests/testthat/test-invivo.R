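test_that("readout-to-FADH conversion is an anchored affine inverse map", {
  s <- bio_readout_series(c(0, 1, 10), c(10, 6, 2), receptor = "cry1",
                         readout_kind = "hypocotyl_length")
  h <- readout_to_fadh(s, readout_dark = 10, readout_saturated = 2)
  expect_equal(h, c(0, 0.5, 1))
  # order-reversing: shorter hypocotyl, more signaling state
  expect_true(all(diff(order(s$readout, decreasing = TRUE)) ==
                    diff(order(h))))
  # inverting the affine map returns the readouts exactly
  back <- 10 - h * (10 - 2)
  expect_equal(back, s$readout, tolerance = 1e-12)
  # default anchors: zero-fluence readout and series minimum
  expect_equal(readout_to_fadh(s), c(0, 0.5, 1))
  expect_error(readout_to_fadh(s, 5, 5), "degenerate")
})

test_that("steady-state inversion satisfies the steady-state equation", {
  k1b <- 0.0023
  for (h in c(0.1, 0.3, 0.475, 0.9)) {
    k1 <- k1b * h / (1 - h)
    expect_equal(steady_state(rate_constants(k1 = k1,
                                             k1b = k1b))[["fadh_rad"]],
                 h, tolerance = 1e-12)
  }
})

test_that("noiseless in vivo blue series recovers the generating phi1", {
  # cry2 degradation assay: 30-min exposure, finite-t inversion
  phi2 <- quantum_yield(4.8e-4, 509.4)
  ser <- generate_invivo_readouts(c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10), 4.8e-4,
                                  "cry2", "protein_level", "finite_t",
                                  "blue", noise_sd = 0)
  tr <- attr(ser, "truth")
  res <- invivo_blue_quantum_yield(ser, exposure_mode = "finite_t",
                                   t_illum = 1800,
                                   readout_dark = tr$readout_dark,
                                   readout_saturated = tr$readout_saturated)
  expect_equal(res$phi, phi2, tolerance = 1e-6)
  expect_equal(res$sigma, 4.8e-4, tolerance = 1e-6)
  # cry1 hypocotyl assay: steady-state inversion
  phi1 <- quantum_yield(2.08e-5, 641.55)
  ser1 <- generate_invivo_readouts(c(0, 0.1, 0.3, 1, 3, 10, 30, 100),
                                   2.08e-5, "cry1", "hypocotyl_length",
                                   "steady_state", "blue", noise_sd = 0)
  tr1 <- attr(ser1, "truth")
  res1 <- invivo_blue_quantum_yield(ser1, exposure_mode = "steady_state",
                                    readout_dark = tr1$readout_dark,
                                    readout_saturated = tr1$readout_saturated)
  expect_equal(res1$phi, phi1, tolerance = 1e-6)
  # a flat series carries no light response
  flat <- bio_readout_series(c(0, 1, 10), rep(10, 3), receptor = "cry2",
                             readout_kind = "protein_level")
  res0 <- invivo_blue_quantum_yield(flat, exposure_mode = "steady_state",
                                    readout_dark = 10,
                                    readout_saturated = 1)
  expect_equal(res0$sigma, 0)
  expect_equal(res0$phi, 0)
})

test_that("noiseless in vivo green series recovers the generating phi2", {
  k1 <- 4.8e-4 * 10 # blue-driven rate at the fixed co-illumination
  phi_true <- quantum_yield(3e-5, 254.7)
  ser <- generate_invivo_readouts(c(0, 10, 25, 50, 100, 250, 500), 3e-5,
                                  "cry2", "protein_level", "finite_t",
                                  "green", k1 = k1, noise_sd = 0)
  tr <- attr(ser, "truth")
  res <- invivo_green_quantum_yield(ser, k1 = k1,
                                    exposure_mode = "finite_t",
                                    t_illum = 1800,
                                    readout_dark = tr$readout_dark,
                                    readout_saturated = tr$readout_saturated)
  expect_equal(res$phi, phi_true, tolerance = 1e-6)
  # zero green fluence implies k2 = 0
  expect_equal(attr(res, "k2")[1], 0, tolerance = 1e-10)
  # readouts increasing with green fluence (FADH rising) are inconsistent
  bad <- ser
  bad$readout <- rev(sort(bad$readout))
  expect_error(invivo_green_quantum_yield(bad, k1 = k1,
                                          exposure_mode = "finite_t",
                                          t_illum = 1800,
                                          readout_dark = tr$readout_dark,
                                          readout_saturated = tr$readout_saturated),
               "inconsistent")
})

test_that("green analysis requires blue co-illumination", {
  ser <- bio_readout_series(c(0, 10), c(1, 0.9), receptor = "cry2",
                            readout_kind = "protein_level",
                            co_fluence_blue = 0)
  expect_error(invivo_green_quantum_yield(ser, k1 = 0.0048),
               "co_fluence_blue")
})

test_that("in vivo generator anchors and monotonicity behave", {
  ser <- generate_invivo_readouts(c(0, 1, 10, 100), 2.08e-5, "cry1",
                                  "hypocotyl_length", "steady_state",
                                  "blue", noise_sd = 0)
  tr <- attr(ser, "truth")
  # dark point sits at the dark anchor
  expect_equal(ser$readout[1], tr$readout_dark)
  # FADH nondecreasing with fluence; readout nonincreasing
  expect_true(all(diff(tr$fadh) >= 0))
  expect_true(all(diff(ser$readout) <= 0))
  # determinism under a fixed seed
  a <- generate_invivo_readouts(c(0, 1, 10), 4.8e-4, "cry2",
                                "protein_level", "finite_t", "blue",
                                noise_sd = 0.05, seed = 99)
  b <- generate_invivo_readouts(c(0, 1, 10), 4.8e-4, "cry2",
                                "protein_level", "finite_t", "blue",
                                noise_sd = 0.05, seed = 99)
  expect_identical(a$readout, b$readout)
})

test_that("readout CSV round trip preserves the series", {
  ser <- generate_invivo_readouts(c(0, 1, 10), 4.8e-4, "cry2",
                                  "protein_level", "finite_t", "blue",
                                  noise_sd = 0.02, seed = 3)
  path <- file.path(withr::local_tempdir(), "readouts.csv")
  write_readout_csv(ser, path, extra = list(exposure_mode = "finite_t"))
  back <- read_readout_csv(path)
  expect_identical(back$readout, ser$readout)
  expect_identical(back$fluence, ser$fluence)
  expect_identical(back$receptor, ser$receptor)
  expect_identical(attr(back, "meta")$exposure_mode, "finite_t")
})
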