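test_that("photocycle derivative matches the kinetic equations", {
  # no dynamics without rates
  expect_equal(unname(photocycle_derivative(state_vector(1, 0, 0),
                                            rate_constants())),
               c(0, 0, 0))
  # single active photoreduction term
  d <- photocycle_derivative(state_vector(1, 0, 0),
                             rate_constants(k1 = 0.01))
  expect_equal(unname(d), c(-0.01, 0.01, 0))
  # radical both drains to FADH- and reoxidizes
  d <- photocycle_derivative(state_vector(0, 1, 0),
                             rate_constants(k2 = 0.02, k1b = 0.005))
  expect_equal(unname(d), c(0.005, -0.025, 0.02))
  # derivative components always cancel (mass conservation)
  set.seed(11)
  for (i in 1:20) {
    x <- stats::runif(3); x <- x / sum(x)
    r <- rate_constants(stats::runif(1, 0, 0.1), stats::runif(1, 0, 0.1),
                        stats::runif(1, 0, 0.1), stats::runif(1, 0, 0.1))
    expect_lt(abs(sum(photocycle_derivative(state_vector(x[1], x[2], x[3]),
                                            r))), 1e-12)
  }
})

test_that("state and rate validation rejects malformed inputs", {
  expect_error(state_vector(0.5, 0.2, 0.2), "sum to 1")
  expect_error(state_vector(1.2, -0.2, 0), "0, 1")
  expect_error(rate_constants(k1 = -0.01), ">= 0")
})

test_that("simulation agrees with a matrix-exponential oracle", {
  grid <- expand.grid(k1 = c(1e-4, 1e-2, 1e-1), k2 = c(0, 1e-2),
                      k1b = c(0, 3e-3, 1e-1), k2b = c(0, 1.1e-2))
  times <- c(10, 100, 2000)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    r <- rate_constants(grid$k1[i], grid$k2[i], grid$k1b[i], grid$k2b[i])
    traj <- simulate_photocycle(r, times = times, step = 0.1)
    for (j in seq_along(times)) {
      ref <- oracle_state(grid$k1[i], grid$k2[i], grid$k1b[i], grid$k2b[i],
                          times[j])
      worst <- max(worst, max(abs(as.numeric(traj[j, 2:4]) - ref)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("trajectories conserve total concentration", {
  r <- rate_constants(0.01, 0.002, 0.003, 0.011)
  traj <- simulate_photocycle(r, times = seq(1, 2000, by = 97))
  expect_true(all(abs(rowSums(traj[, 2:4]) - 1) < 1e-9))
  # equilibrium stays put
  traj0 <- simulate_photocycle(rate_constants(), times = c(5, 50))
  expect_equal(traj0$fad_ox, c(1, 1))
})

test_that("simulation reduces to the closed forms in the limiting cases", {
  # two-state limit (k2 = k2b = 0)
  traj <- simulate_photocycle(rate_constants(k1 = 0.01, k1b = 0.003),
                              times = 100)
  expect_equal(traj$fadh_rad,
               two_state_concentrations(0.01, 0.003, 100)[["fadh_rad"]],
               tolerance = 1e-6)
  expect_equal(traj$fadh_rad, (0.01 / 0.013) * (1 - exp(-0.013 * 100)),
               tolerance = 1e-6)
  # pure dark decay limit (k1 = k2 = 0)
  s0 <- state_vector(0.2, 0.8, 0)
  traj <- simulate_photocycle(rate_constants(k1b = 0.01),
                              initial = s0, times = c(50, 200, 600))
  ref <- reoxidation_decay(reoxidation_curve_params(0.2, 0.8, 0.01),
                           td = c(50, 200, 600))
  expect_equal(traj$fadh_rad, ref$fadh_rad, tolerance = 1e-6)
  expect_equal(traj$fad_ox, ref$fad_ox, tolerance = 1e-6)
})

test_that("simulation rejects bad arguments", {
  expect_error(simulate_photocycle(rate_constants(), times = c(5, 2)),
               "increasing")
  expect_error(simulate_photocycle(rate_constants(), times = 10, step = 0),
               "positive")
})

test_that("two-state closed form has the right anchors and monotonicity", {
  expect_equal(unname(two_state_concentrations(0.37, 0.11, 0)), c(1, 0))
  # irreversible limit saturates at full conversion
  expect_equal(two_state_concentrations(0.01, 0, 1e7)[["fadh_rad"]], 1,
               tolerance = 1e-9)
  expect_equal(two_state_concentrations(0.002, 0.003, 200)[["fadh_rad"]],
               0.4 * (1 - exp(-1)), tolerance = 1e-12)
  # nondecreasing in t and in k1
  ts <- seq(0, 500, by = 25)
  h_t <- two_state_concentrations(0.01, 0.003, ts)$fadh_rad
  expect_true(all(diff(h_t) >= 0))
  k1s <- 10^seq(-4, 0, length.out = 30)
  h_k <- vapply(k1s, function(k)
    two_state_concentrations(k, 0.003, 20)[["fadh_rad"]], numeric(1))
  expect_true(all(diff(h_k) > 0))
})

test_that("dark reoxidation decay follows first-order kinetics", {
  p <- reoxidation_curve_params(0, 1, 0.003)
  expect_equal(unname(reoxidation_decay(p, 0)), c(0, 1))
  # half the radical remains after one half-life (~231 s at 0.003 s^-1)
  expect_equal(reoxidation_decay(p, 231)[["fadh_rad"]], 0.5,
               tolerance = 1e-3)
  # complete reoxidation restores all flavin to FADox
  p2 <- reoxidation_curve_params(0.2, 0.8, 0.01)
  expect_equal(unname(reoxidation_decay(p2, 1e7)), c(1, 0),
               tolerance = 1e-12)
  # total concentration c_ox + c_o conserved along the decay
  d <- reoxidation_decay(p2, seq(0, 1000, by = 100))
  expect_true(all(abs(d$fad_ox + d$fadh_rad - 1) < 1e-12))
  expect_error(reoxidation_decay(p, -5), ">= 0")
})

test_that("half-life is ln(2)/k", {
  expect_equal(round(half_life(0.003)), 231)
  expect_equal(round(half_life(0.013)), 53)
  expect_equal(half_life(log(2)), 1)
  # identity k * half_life = ln 2, exactly
  for (k in c(1e-4, 0.003, 0.016, 2))
    expect_identical(half_life(k) * k, log(2))
  expect_error(half_life(0), "> 0")
  expect_error(half_life(-1), "> 0")
})

test_that("steady state zeroes the derivative and matches known limits", {
  expect_equal(unname(unclass(steady_state(rate_constants(k1b = 0.003)))),
               c(1, 0, 0))
  expect_equal(steady_state(rate_constants(k1 = 0.003,
                                           k1b = 0.003))[["fadh_rad"]], 0.5)
  r <- rate_constants(0.01, 0.002, 0.003, 0.011)
  ss <- steady_state(r)
  expect_lt(max(abs(photocycle_derivative(ss, r))), 1e-12)
  # long-time integration converges to it
  late <- simulate_photocycle(r, times = 1e4, step = 0.5)
  expect_lt(max(abs(as.numeric(late[, 2:4]) - unclass(ss))), 1e-6)
  expect_error(steady_state(rate_constants()), "all rates are zero")
  expect_error(steady_state(rate_constants(k1 = 0.01)), "degenerate")
  expect_error(steady_state(rate_constants(k1 = 0.01, k2 = 0.01,
                                           k1b = 0.003)), "degenerate")
})
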