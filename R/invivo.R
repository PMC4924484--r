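# In vivo analysis: biological readouts (hypocotyl length for cry1, cry2
# protein level for cry2) stand in for the FADH° signaling-state
# concentration, which cannot be measured directly in living seedlings.
# The readout is mapped to normalized FADH° by an affine inverse relation
# anchored at the dark and light-saturated readouts, then the same two- and
# three-state inversion machinery as in vitro yields cross sections and
# quantum yields.

#' Construct an in vivo dose-response series
#'
#' @param fluence Photon fluence rates (µmol m^-2 s^-1), >= 0.
#' @param readout Measured biological readouts (> 0): hypocotyl lengths or
#'   relative protein band intensities.
#' @param stderr Standard errors of the readouts (same units); optional.
#' @param readout_kind `"hypocotyl_length"` or `"protein_level"`.
#' @param receptor `"cry1"` or `"cry2"`.
#' @param co_fluence_blue Fixed blue co-illumination (µmol m^-2 s^-1) for
#'   green-light series; 0 for pure blue series.
#' @return A list of class `"bio_readout_series"`.
#' @export
bio_readout_series <- function(fluence, readout, stderr = NULL,
                               readout_kind = c("hypocotyl_length",
                                                "protein_level"),
                               receptor = c("cry1", "cry2"),
                               co_fluence_blue = 0) {
  readout_kind <- match.arg(readout_kind)
  receptor <- match.arg(receptor)
  if (length(fluence) != length(readout))
    stop("fluence and readout must have the same length", call. = FALSE)
  if (any(fluence < 0)) stop("fluence rates must be >= 0", call. = FALSE)
  if (any(readout <= 0)) stop("readouts must be > 0", call. = FALSE)
  if (!is.null(stderr) && length(stderr) != length(readout))
    stop("stderr must match readout length", call. = FALSE)
  structure(list(fluence = as.numeric(fluence),
                 readout = as.numeric(readout),
                 stderr = if (is.null(stderr)) rep(NA_real_, length(readout))
                          else as.numeric(stderr),
                 readout_kind = readout_kind, receptor = receptor,
                 co_fluence_blue = co_fluence_blue),
            class = "bio_readout_series")
}

#' In vivo literature rate constants
#'
#' Dark reoxidation rates of the FADH° radical measured in planta
#' (cry1 0.0023 s^-1, cry2 7.2e-4 s^-1) and the FADH- reoxidation rate
#' (0.011 s^-1), all overridable.
#'
#' @param k1b_cry1_invivo,k1b_cry2_invivo,k2b Rates in s^-1.
#' @return A list of class `"literature_rates"`.
#' @export
literature_rates <- function(k1b_cry1_invivo = 0.0023,
                             k1b_cry2_invivo = 7.2e-4,
                             k2b = 0.011) {
  vals <- c(k1b_cry1_invivo, k1b_cry2_invivo, k2b)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  structure(list(k1b_cry1_invivo = k1b_cry1_invivo,
                 k1b_cry2_invivo = k1b_cry2_invivo, k2b = k2b),
            class = "literature_rates")
}

invivo_k1b <- function(rates, receptor) {
  stopifnot(inherits(rates, "literature_rates"))
  switch(receptor,
         cry1 = rates$k1b_cry1_invivo,
         cry2 = rates$k1b_cry2_invivo,
         stop("unknown receptor ", receptor, call. = FALSE))
}

#' Convert a biological readout to normalized FADH° concentration
#'
#' The readout is inversely related to signaling-state formation (blue light
#' shortens hypocotyls and degrades cry2 protein). The minimal realization
#' is an affine, order-reversing map anchored at the dark readout (FADH° =
#' 0) and the light-saturated readout (FADH° = 1):
#' `H(I) = (dark - readout(I)) / (dark - saturated)`, clamped to `[0, 1]`.
#'
#' @param series A [bio_readout_series()].
#' @param readout_dark Readout with no illumination; defaults to the readout
#'   at zero fluence if present, otherwise the maximum observed.
#' @param readout_saturated Readout at saturating light; defaults to the
#'   minimum observed (highest fluence approximates saturation).
#' @return Numeric vector of normalized FADH° values, one per fluence.
#' @export
readout_to_fadh <- function(series, readout_dark = NULL,
                            readout_saturated = NULL) {
  stopifnot(inherits(series, "bio_readout_series"))
  if (is.null(readout_dark)) {
    i0 <- which(series$fluence == 0)
    readout_dark <- if (length(i0)) series$readout[i0[1]]
                    else max(series$readout)
  }
  if (is.null(readout_saturated)) readout_saturated <- min(series$readout)
  if (abs(readout_dark - readout_saturated) < 1e-12)
    stop("degenerate calibration: dark and saturated readouts coincide",
         call. = FALSE)
  h <- (readout_dark - series$readout) / (readout_dark - readout_saturated)
  pmin(pmax(h, 0), 1)
}

# Steady-state two-state inversion: H = k1/(k1+k1b) => k1 = k1b H/(1-H)
steady_state_k1 <- function(h, k1b) {
  if (h >= 1)
    stop("FADH concentration of 1 is unattainable at steady state with ",
         "k1b > 0", call. = FALSE)
  k1b * h / (1 - h)
}

# Per-point FADH° standard errors on the normalized scale, from readout
# standard errors and the affine calibration. NULL if no stderr available.
fadh_stderr <- function(series, readout_dark, readout_saturated) {
  if (all(is.na(series$stderr))) return(NULL)
  abs(series$stderr) / abs(readout_dark - readout_saturated)
}

# Inverse-variance weights for the dose-response fit by the delta method:
# Var(k_i) = (dk/dH)_i^2 * Var(H_i). `invert` maps H -> k; its derivative
# is taken numerically at the observed H.
inversion_weights <- function(h, sigma_h, invert) {
  if (is.null(sigma_h)) return(NULL)
  dk_dh <- vapply(h, function(hi) {
    d <- 1e-4
    hi <- min(max(hi, 0), 1 - 2 * d)
    (invert(hi + d) - invert(max(hi - d, 0))) /
      (d + min(hi, d))
  }, numeric(1))
  v <- (dk_dh * sigma_h)^2
  # flat spots (clamped observations) carry no information: weight them
  # like the most uncertain informative point
  if (any(v > 0)) v[v <= 0] <- max(v[v > 0]) else v[] <- 1
  1 / v
}

#' Blue-light quantum yield from an in vivo dose-response series
#'
#' Converts readouts to FADH° concentrations, inverts each fluence point to
#' a rate constant k1 (two-state model), fits the through-origin
#' dose-response `k1 = sigma1 * I1`, and derives the quantum yield with the
#' receptor's in vitro extinction coefficient.
#'
#' Exposure modes: `"steady_state"` treats the illumination as long relative
#' to reoxidation (days of hypocotyl growth; `k1 = k1b H/(1-H)`);
#' `"finite_t"` inverts the two-state solution at the stated illumination
#' time (e.g. 1800 s for the 30-min cry2 degradation assay).
#'
#' @param series A [bio_readout_series()].
#' @param rates A [literature_rates()]; the receptor's in vivo k1b is used.
#' @param eps Extinction coefficient (mol^-1 m^2); defaults to the
#'   receptor's in vitro value.
#' @param exposure_mode `"steady_state"` or `"finite_t"`.
#' @param t_illum Illumination time (s) for `finite_t` mode; default 1800.
#' @param readout_dark,readout_saturated Calibration anchors passed to
#'   [readout_to_fadh()].
#' @return A `"cross_section_result"` for the FADox -> FADH° transition,
#'   with the per-fluence `k1` values attached as attribute `"k1"`.
#' @export
invivo_blue_quantum_yield <- function(series, rates = literature_rates(),
                                      eps = cry_extinction(series$receptor),
                                      exposure_mode = c("steady_state",
                                                        "finite_t"),
                                      t_illum = 1800,
                                      readout_dark = NULL,
                                      readout_saturated = NULL) {
  stopifnot(inherits(series, "bio_readout_series"))
  exposure_mode <- match.arg(exposure_mode)
  if (length(series$fluence) < 2L)
    stop("at least 2 fluence points are required", call. = FALSE)
  k1b <- invivo_k1b(rates, series$receptor)
  if (is.null(readout_dark)) {
    i0 <- which(series$fluence == 0)
    readout_dark <- if (length(i0)) series$readout[i0[1]]
                    else max(series$readout)
  }
  if (is.null(readout_saturated)) readout_saturated <- min(series$readout)
  h <- readout_to_fadh(series, readout_dark, readout_saturated)
  invert <- function(hi) {
    if (hi <= 0) return(0)
    if (exposure_mode == "steady_state") steady_state_k1(hi, k1b)
    else infer_k1(min(hi, 1 - 1e-12), "fadh_rad", t_illum, k1b)
  }
  k1 <- vapply(h, invert, numeric(1))
  w <- inversion_weights(h, fadh_stderr(series, readout_dark,
                                        readout_saturated), invert)
  fit <- fit_cross_section(series$fluence, k1, weights = w)
  res <- cross_section_result(fit, eps, "ox_to_radical", "fadh_rad")
  attr(res, "k1") <- k1
  attr(res, "fadh") <- h
  res
}

# Steady-state FADH° of the full three-state system as a function of k2
steady_state_fadh <- function(k1, k2, k1b, k2b) {
  steady_state(rate_constants(k1, k2, k1b, k2b))[["fadh_rad"]]
}

#' Green-light quantum yield from an in vivo co-illumination series
#'
#' For a series measured under fixed blue co-illumination and increasing
#' green fluence rates, inverts each point to a rate constant k2 with the
#' three-state model (using `k1` from the blue-light stage and the
#' literature reoxidation rates), fits `k2 = sigma2 * I2` through the
#' origin, and derives the quantum yield with `eps2 = eps_ox(450)/2`.
#'
#' @param series A [bio_readout_series()] with `co_fluence_blue > 0`.
#' @param k1 Blue photoreduction rate (s^-1) at the series'
#'   `co_fluence_blue`, from the blue-light analysis.
#' @param rates A [literature_rates()].
#' @param eps2 FADH° extinction (mol^-1 m^2); defaults to half the
#'   receptor's oxidized-flavin extinction.
#' @param exposure_mode,t_illum As in [invivo_blue_quantum_yield()].
#' @param consistency_tol Slack allowed above the `k2 = 0` prediction (and
#'   for a positive FADH°-vs-fluence trend) before data are declared
#'   inconsistent with green-light depletion; set to ~3x the FADH° noise sd
#'   for noisy readouts. Default 0.02.
#' @param readout_dark,readout_saturated Calibration anchors; for a green
#'   series the "dark" anchor is the readout at zero green fluence (blue
#'   only, maximal FADH° depletion of the readout) — the defaults of
#'   [readout_to_fadh()] apply to the green-series convention below.
#' @details The green series anchors differ from the blue series: at zero
#'   green fluence FADH° is maximal (blue-driven), and increasing green
#'   light depletes it. Anchors should therefore be supplied on the same
#'   normalized scale used when generating or measuring the readouts; by
#'   default the affine map of [readout_to_fadh()] is used unchanged and the
#'   inferred FADH° is checked for monotone decrease with green fluence.
#' @return A `"cross_section_result"` for the FADH° -> FADH- transition
#'   with per-fluence `k2` attached as attribute `"k2"`.
#' @export
invivo_green_quantum_yield <- function(series, k1,
                                       rates = literature_rates(),
                                       eps2 = cry_extinction(series$receptor) / 2,
                                       exposure_mode = c("steady_state",
                                                         "finite_t"),
                                       t_illum = 1800,
                                       readout_dark = NULL,
                                       readout_saturated = NULL,
                                       consistency_tol = 0.02) {
  stopifnot(inherits(series, "bio_readout_series"))
  exposure_mode <- match.arg(exposure_mode)
  if (series$co_fluence_blue <= 0)
    stop("green-light analysis requires fixed blue co-illumination ",
         "(co_fluence_blue > 0)", call. = FALSE)
  k1b <- invivo_k1b(rates, series$receptor)
  k2b <- rates$k2b
  if (is.null(readout_saturated)) readout_saturated <- min(series$readout)
  if (is.null(readout_dark)) readout_dark <- max(series$readout)
  h <- readout_to_fadh(series, readout_dark, readout_saturated)
  if (length(h) >= 3) {
    sl <- stats::lm(h ~ series$fluence)
    cf <- summary(sl)$coefficients
    if (cf[2, 1] > 0 && cf[2, 1] * max(series$fluence) > consistency_tol &&
        cf[2, 4] < 0.05)
      stop("FADH concentration increases with green fluence: data ",
           "inconsistent with green-light depletion of the radical",
           call. = FALSE)
  }
  h0 <- if (exposure_mode == "steady_state")
    steady_state_fadh(k1, 0, k1b, k2b)
  else simulate_photocycle(rate_constants(k1, 0, k1b, k2b),
                           times = t_illum)$fadh_rad
  if (any(h > h0 + consistency_tol))
    stop("observed FADH exceeds the zero-green prediction by more than ",
         consistency_tol, ": data inconsistent with the three-state model",
         call. = FALSE)
  invert <- function(hi) {
    hi <- min(hi, h0)
    if (exposure_mode == "steady_state") {
      f <- function(k2) steady_state_fadh(k1, k2, k1b, k2b) - hi
      if (f(0) <= 0) return(0)
      find_rate_root(f, k_init = max(k1, 1e-3))
    } else {
      infer_k2(hi, t_illum, k1, k1b, k2b, tol = consistency_tol)
    }
  }
  k2 <- vapply(h, invert, numeric(1))
  w <- inversion_weights(h, fadh_stderr(series, readout_dark,
                                        readout_saturated), invert)
  fit <- fit_cross_section(series$fluence, k2, weights = w)
  res <- cross_section_result(fit, eps2, "radical_to_reduced", "fadh_rad")
  attr(res, "k2") <- k2
  attr(res, "fadh") <- h
  res
}
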