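# Synthetic data with known ground truth: photoreduction/reoxidation
# spectral series, blue and green dose-response experiments, and in vivo
# readout series. The generators emulate the study designs (20-30 s
# illuminations, fluence rates spanning 10-4000 µmol m^-2 s^-1 blue and
# 0-1000 green, dark sampling over >= 3 half-lives) with additive Gaussian
# noise on absorbance, and attach the generating parameters so recovery can
# be scored automatically.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a cry2-at-pH-7.5-like experiment: sigma1 = 1.6e-4 and
#' sigma2 = 1.6e-5 µmol^-1 m^2, k1b = 0.003 s^-1, k2b = 0.011 s^-1,
#' extinction 509.4 mol^-1 m^2, 20-s illuminations at 200 µmol m^-2 s^-1,
#' blue dose series over 25-400 µmol m^-2 s^-1, green dose series 0-1000
#' under 100 µmol m^-2 s^-1 blue, dark recovery sampled to ~3 half-lives,
#' and 1% absorbance noise.
#'
#' @param sigma1_true,sigma2_true Generating photoconversion cross sections
#'   (µmol^-1 m^2).
#' @param k1b_true,k2b_true Generating reoxidation rates (s^-1).
#' @param eps An [extinction_set()].
#' @param noise_sd Additive Gaussian noise on normalized absorbance (AU).
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @param wavelengths Spectral grid (nm) within 400-570.
#' @param t_illum Illumination duration (s).
#' @param fluence_illum Fluence rate for the single-illumination
#'   (reoxidation) experiment (µmol m^-2 s^-1).
#' @param blue_fluences Blue dose-series fluence rates.
#' @param green_fluences Green dose-series fluence rates (must include 0).
#' @param blue_co_fluence Fixed blue fluence during the green series.
#' @param dark_times Dark-recovery sampling times (s).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(sigma1_true = 1.6e-4,
                             sigma2_true = 1.6e-5,
                             k1b_true = 0.003,
                             k2b_true = 0.011,
                             eps = extinction_set(cry_extinction("cry2")),
                             noise_sd = 0.01,
                             seed = 1L,
                             wavelengths = seq(400, 570, by = 1),
                             t_illum = 20,
                             fluence_illum = 200,
                             blue_fluences = c(25, 50, 100, 200, 400),
                             green_fluences = c(0, 50, 100, 200, 500, 1000),
                             blue_co_fluence = 100,
                             dark_times = seq(0, 750, by = 50)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(eps, "extinction_set"))
  structure(list(sigma1_true = sigma1_true, sigma2_true = sigma2_true,
                 k1b_true = k1b_true, k2b_true = k2b_true, eps = eps,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 wavelengths = wavelengths, t_illum = t_illum,
                 fluence_illum = fluence_illum,
                 blue_fluences = blue_fluences,
                 green_fluences = green_fluences,
                 blue_co_fluence = blue_co_fluence,
                 dark_times = dark_times),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Stand-in extinction basis spectra
#'
#' Smooth Gaussian-mixture curves for the per-species extinctions over the
#' 400-570 nm window, built to satisfy exactly the constraints the
#' two-wavelength deconvolution relies on: the FADox curve peaks at 450 nm
#' at the configured value and is negligible at 560 nm; the FADH° curve is a
#' symmetric two-Gaussian mixture equal at 450 and 560 nm to half the FADox
#' peak; FADH- is identically zero in this window. They are stand-ins, not
#' literature flavin spectra — only these constraints matter for the math.
#'
#' @param wavelengths Grid (nm) within 400-570.
#' @param eps_ox_450 FADox peak extinction at 450 nm (mol^-1 m^2).
#' @return Data frame with columns `wavelength`, `eps_ox`, `eps_h`,
#'   `eps_hminus`.
#' @export
synth_basis_spectra <- function(wavelengths, eps_ox_450 = 509.4) {
  if (min(wavelengths) < 400 || max(wavelengths) > 570)
    stop("wavelength grid must lie within 400-570 nm", call. = FALSE)
  gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
  # narrow FADox band: at 560 nm the contribution underflows (~1e-12 of
  # peak), keeping noiseless round trips exact
  eps_ox <- eps_ox_450 * gauss(wavelengths, 450, 15)
  # symmetric mixture: equal at 450 and 560 by construction
  mix <- gauss(wavelengths, 450, 30) + gauss(wavelengths, 560, 30)
  mix_at_450 <- gauss(450, 450, 30) + gauss(450, 560, 30)
  eps_h <- (eps_ox_450 / 2) * mix / mix_at_450
  data.frame(wavelength = wavelengths, eps_ox = eps_ox, eps_h = eps_h,
             eps_hminus = 0)
}

# Render one normalized spectrum from a state; normalization is to the dark
# spectrum's A(450) = eps_ox(450) (all flavin oxidized).
render_spectrum <- function(state, basis, eps_ox_450, time, condition,
                            fluence_blue = 0, fluence_green = 0,
                            noise_sd = 0) {
  s <- as_state_vector(state)
  a <- (s[["fad_ox"]] * basis$eps_ox + s[["fadh_rad"]] * basis$eps_h) /
    eps_ox_450
  if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
  spectrum_record(basis$wavelength, a, time = time, condition = condition,
                  fluence_blue = fluence_blue, fluence_green = fluence_green)
}

#' Generate a photoreduction + dark-recovery spectral series
#'
#' Simulates a blue illumination of the configured duration and fluence
#' rate, then dark reoxidation sampled at the configured dark times, and
#' renders each state as a normalized absorbance spectrum (plus noise). The
#' first record is the dark spectrum before illumination.
#'
#' @param config A [synthetic_config()].
#' @return List of [spectrum_record()]s with attribute `"truth"` (the
#'   generating parameters, including the state at the start of darkness).
#' @export
generate_reoxidation_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  basis <- synth_basis_spectra(config$wavelengths, config$eps$eps_ox_450)
  k1 <- config$sigma1_true * config$fluence_illum
  illum <- simulate_photocycle(
    rate_constants(k1 = k1, k1b = config$k1b_true),
    times = config$t_illum)
  s0 <- state_vector(illum$fad_ox, illum$fadh_rad, illum$fadh_minus)
  dark_rates <- rate_constants(k1b = config$k1b_true, k2b = config$k2b_true)
  td <- config$dark_times
  states <- if (td[1] == 0 && length(td) == 1L) {
    list(s0)
  } else {
    traj <- simulate_photocycle(dark_rates, initial = s0,
                                times = td[td > 0])
    out <- lapply(seq_len(nrow(traj)), function(i)
      state_vector(traj$fad_ox[i], traj$fadh_rad[i], traj$fadh_minus[i]))
    if (td[1] == 0) c(list(s0), out) else out
  }
  with_seed(config$seed, {
    dark_rec <- render_spectrum(state_vector(1, 0, 0), basis,
                                config$eps$eps_ox_450, time = 0,
                                condition = "dark_initial",
                                noise_sd = config$noise_sd)
    recs <- lapply(seq_along(td), function(i)
      render_spectrum(states[[i]], basis, config$eps$eps_ox_450,
                      time = td[i], condition = "dark_recovery",
                      noise_sd = config$noise_sd))
    series <- c(list(dark_rec), recs)
    attr(series, "truth") <- list(
      k1b = config$k1b_true, k2b = config$k2b_true, k1_illum = k1,
      c_ox = s0[["fad_ox"]], c_o = s0[["fadh_rad"]],
      t_illum = config$t_illum, fluence_illum = config$fluence_illum,
      noise_sd = config$noise_sd, seed = config$seed)
    series
  })
}

#' Generate a blue-light dose-response spectral series
#'
#' One spectrum per blue fluence rate, each taken at the end of a 20-30 s
#' illumination with `k1 = sigma1_true * I1` (two-state conditions, k2 = 0).
#' A zero fluence, if present, yields the dark spectrum (plus noise).
#'
#' @param config A [synthetic_config()].
#' @return List of [spectrum_record()]s (first record is the dark
#'   reference), with attribute `"truth"`.
#' @export
generate_blue_dose_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$blue_fluences) < 2L ||
      anyDuplicated(config$blue_fluences))
    stop("blue fluence rates must be distinct, with at least 2 values",
         call. = FALSE)
  basis <- synth_basis_spectra(config$wavelengths, config$eps$eps_ox_450)
  states <- lapply(config$blue_fluences, function(I1) {
    k1 <- config$sigma1_true * I1
    tr <- simulate_photocycle(rate_constants(k1 = k1, k1b = config$k1b_true),
                              times = config$t_illum)
    state_vector(tr$fad_ox, tr$fadh_rad, tr$fadh_minus)
  })
  with_seed(config$seed, {
    dark_rec <- render_spectrum(state_vector(1, 0, 0), basis,
                                config$eps$eps_ox_450, time = 0,
                                condition = "dark_initial",
                                noise_sd = config$noise_sd)
    recs <- lapply(seq_along(config$blue_fluences), function(i)
      render_spectrum(states[[i]], basis, config$eps$eps_ox_450,
                      time = config$t_illum, condition = "illuminated_blue",
                      fluence_blue = config$blue_fluences[i],
                      noise_sd = config$noise_sd))
    series <- c(list(dark_rec), recs)
    attr(series, "truth") <- list(
      sigma1 = config$sigma1_true, k1b = config$k1b_true,
      t_illum = config$t_illum, fluences = config$blue_fluences,
      noise_sd = config$noise_sd, seed = config$seed)
    series
  })
}

#' Generate a green-light co-illumination dose-response series
#'
#' One spectrum per green fluence rate under fixed blue co-illumination:
#' `k1 = sigma1_true * blue_co_fluence` and `k2 = sigma2_true * I2`. At the
#' study's parameter scale the green series depletes FADH° while FADox
#' stays nearly constant.
#'
#' @param config A [synthetic_config()]; `green_fluences` must include 0.
#' @param neglect_reoxidation Generate with `k1b = k2b = 0` (the reduced
#'   short-illumination mode); default TRUE, matching how the series is
#'   analyzed at 20-s illuminations.
#' @return List of [spectrum_record()]s (first record dark), with attribute
#'   `"truth"`.
#' @export
generate_green_dose_series <- function(config, neglect_reoxidation = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!any(config$green_fluences == 0))
    stop("green fluence rates must include 0", call. = FALSE)
  basis <- synth_basis_spectra(config$wavelengths, config$eps$eps_ox_450)
  k1 <- config$sigma1_true * config$blue_co_fluence
  k1b <- if (neglect_reoxidation) 0 else config$k1b_true
  k2b <- if (neglect_reoxidation) 0 else config$k2b_true
  states <- lapply(config$green_fluences, function(I2) {
    k2 <- config$sigma2_true * I2
    tr <- simulate_photocycle(rate_constants(k1, k2, k1b, k2b),
                              times = config$t_illum)
    state_vector(tr$fad_ox, tr$fadh_rad, tr$fadh_minus)
  })
  with_seed(config$seed, {
    dark_rec <- render_spectrum(state_vector(1, 0, 0), basis,
                                config$eps$eps_ox_450, time = 0,
                                condition = "dark_initial",
                                noise_sd = config$noise_sd)
    recs <- lapply(seq_along(config$green_fluences), function(i)
      render_spectrum(states[[i]], basis, config$eps$eps_ox_450,
                      time = config$t_illum,
                      condition = "illuminated_blue_green",
                      fluence_blue = config$blue_co_fluence,
                      fluence_green = config$green_fluences[i],
                      noise_sd = config$noise_sd))
    series <- c(list(dark_rec), recs)
    attr(series, "truth") <- list(
      sigma1 = config$sigma1_true, sigma2 = config$sigma2_true,
      k1 = k1, k1b = k1b, k2b = k2b, t_illum = config$t_illum,
      blue_co_fluence = config$blue_co_fluence,
      fluences = config$green_fluences,
      noise_sd = config$noise_sd, seed = config$seed)
    series
  })
}

#' Generate an in vivo dose-response readout series
#'
#' Produces biological readouts (hypocotyl length or relative protein
#' level) from the generating kinetics: normalized FADH° per fluence
#' (steady-state or finite-exposure two-/three-state model), mapped through
#' the inverse affine readout relation anchored at the dark and saturated
#' readouts, plus Gaussian noise.
#'
#' @param fluences Photon fluence rates (µmol m^-2 s^-1). For
#'   `light = "green"` these are green fluences (must include 0) under
#'   fixed blue co-illumination.
#' @param sigma_true Generating cross section (µmol^-1 m^2) of the probed
#'   transition (sigma1 for blue, sigma2 for green).
#' @param receptor `"cry1"` or `"cry2"`.
#' @param readout_kind `"hypocotyl_length"` or `"protein_level"`.
#' @param exposure_mode `"steady_state"` or `"finite_t"`.
#' @param light `"blue"` or `"green"`.
#' @param rates A [literature_rates()] for the reoxidation constants.
#' @param k1 Blue photoreduction rate (s^-1) for green series (fixed blue
#'   co-illumination); ignored for blue series.
#' @param blue_co_fluence Blue co-illumination fluence (green series).
#' @param t_illum Illumination time (s) in `finite_t` mode.
#' @param readout_dark,readout_saturated Anchor readouts; defaults 10 and 2
#'   (mm) for hypocotyls, 1 and 0.1 (relative units) for protein level.
#' @param noise_sd Gaussian noise sd in readout units (0 = noiseless).
#' @param seed RNG seed.
#' @return A [bio_readout_series()] with attribute `"truth"`.
#' @export
generate_invivo_readouts <- function(fluences, sigma_true,
                                     receptor = c("cry2", "cry1"),
                                     readout_kind = c("protein_level",
                                                      "hypocotyl_length"),
                                     exposure_mode = c("finite_t",
                                                       "steady_state"),
                                     light = c("blue", "green"),
                                     rates = literature_rates(),
                                     k1 = NULL, blue_co_fluence = 10,
                                     t_illum = 1800,
                                     readout_dark = NULL,
                                     readout_saturated = NULL,
                                     noise_sd = 0, seed = NULL) {
  receptor <- match.arg(receptor)
  readout_kind <- match.arg(readout_kind)
  exposure_mode <- match.arg(exposure_mode)
  light <- match.arg(light)
  if (is.null(readout_dark))
    readout_dark <- if (readout_kind == "hypocotyl_length") 10 else 1
  if (is.null(readout_saturated))
    readout_saturated <- if (readout_kind == "hypocotyl_length") 2 else 0.1
  if (abs(readout_dark - readout_saturated) < 1e-12)
    stop("degenerate anchors", call. = FALSE)
  k1b <- invivo_k1b(rates, receptor)
  h <- if (light == "blue") {
    vapply(fluences, function(I1) {
      ki <- sigma_true * I1
      if (exposure_mode == "steady_state") {
        if (ki == 0) 0 else ki / (ki + k1b)
      } else {
        two_state_concentrations(ki, k1b, t_illum)[["fadh_rad"]]
      }
    }, numeric(1))
  } else {
    if (is.null(k1))
      stop("green series needs the blue-driven k1", call. = FALSE)
    if (!any(fluences == 0))
      stop("green fluences must include 0", call. = FALSE)
    vapply(fluences, function(I2) {
      k2 <- sigma_true * I2
      if (exposure_mode == "steady_state")
        steady_state_fadh(k1, k2, k1b, rates$k2b)
      else
        simulate_photocycle(rate_constants(k1, k2, k1b, rates$k2b),
                            times = t_illum)$fadh_rad
    }, numeric(1))
  }
  readout <- readout_dark - h * (readout_dark - readout_saturated)
  with_seed(seed, {
    if (noise_sd > 0)
      readout <- readout + stats::rnorm(length(readout), 0, noise_sd)
    readout <- pmax(readout, 1e-6)
    series <- bio_readout_series(
      fluences, readout,
      stderr = rep(max(noise_sd, 1e-6), length(readout)),
      readout_kind = readout_kind, receptor = receptor,
      co_fluence_blue = if (light == "green") blue_co_fluence else 0)
    attr(series, "truth") <- list(
      sigma_true = sigma_true, k1b = k1b, k2b = rates$k2b, k1 = k1,
      exposure_mode = exposure_mode, light = light, t_illum = t_illum,
      fadh = h, readout_dark = readout_dark,
      readout_saturated = readout_saturated, noise_sd = noise_sd,
      seed = seed)
    series
  })
}
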