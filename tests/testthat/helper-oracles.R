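# Independent oracles and small fixture builders used across tests.

# Matrix exponential of the kinetic system (independent of the package's
# RK4 propagator): truncated Taylor series with scaling and squaring.
expm_taylor <- function(A, order = 24, squarings = 20) {
  B <- A / 2^squarings
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% B / i
    S <- S + term
  }
  for (i in seq_len(squarings)) S <- S %*% S
  S
}

# State at time t from the linear system, via the matrix exponential
oracle_state <- function(k1, k2, k1b, k2b, t, x0 = c(1, 0, 0)) {
  A <- matrix(c(-k1, k1b, k2b,
                k1, -(k2 + k1b), 0,
                0, k2, -k2b), nrow = 3, byrow = TRUE)
  if (requireNamespace("Matrix", quietly = TRUE)) {
    drop(as.matrix(Matrix::expm(A * t)) %*% x0)
  } else {
    drop(expm_taylor(A * t) %*% x0)
  }
}

# Analyze a synthetic blue dose series end to end, returning the fitted
# cross section (tol widened for noisy data).
recover_sigma1 <- function(config, species = "fadh_rad", tol = 0.1) {
  ser <- generate_blue_dose_series(config)
  ser <- normalize_to_dark(ser, ser[[1]])
  conc <- series_concentrations(ser[-1], tol = tol)
  k1 <- vapply(seq_len(nrow(conc)), function(i) {
    obs <- if (species == "fadh_rad") min(conc$fadh_rad[i], 1 - 1e-12)
           else max(conc$fad_ox[i], 1e-12)
    infer_k1(obs, species, config$t_illum, config$k1b_true)
  }, numeric(1))
  fit_cross_section(config$blue_fluences, k1)
}

recover_sigma2 <- function(config, tol = 0.1) {
  ser <- generate_green_dose_series(config)
  ser <- normalize_to_dark(ser, ser[[1]])
  conc <- series_concentrations(ser[-1], tol = tol)
  k1 <- config$sigma1_true * config$blue_co_fluence
  k2 <- vapply(seq_len(nrow(conc)), function(i)
    infer_k2(conc$fadh_rad[i], config$t_illum, k1, tol = tol),
    numeric(1))
  fit_cross_section(config$green_fluences, k2)
}

recover_k1b <- function(config, species = "fadh_rad", tol = 0.1) {
  ser <- generate_reoxidation_series(config)
  ser <- normalize_to_dark(ser, ser[[1]])
  conc <- series_concentrations(ser[-1], tol = tol)
  fit_reoxidation(conc$time, conc[[species]], species = species)
}
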