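# Inverse machinery: dark-reoxidation fitting, two-state and three-state
# rate inversion, through-origin dose-response fits, quantum yields.

#' Fit the dark-reoxidation decay
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of a dark-recovery
#' concentration time course with the first-order reoxidation model:
#' `fadh_rad(td) = c_o exp(-k1b td)` or
#' `fad_ox(td) = c_ox + c_o (1 - exp(-k1b td))`.
#'
#' Starting values: `c_o` from the first observation (or the observed span
#' for FADox fits) and `k1b` from a log-linear regression of the decaying
#' part.
#'
#' @param td Dark times (s), >= 0, increasing; at least 3 points.
#' @param conc Observed normalized concentrations, same length.
#' @param species `"fadh_rad"` (decay) or `"fad_ox"` (recovery).
#' @return A list of class `"reoxidation_fit"`: `k1b`, `c_o`, `c_ox`
#'   (NA for radical fits), `half_life` (s), `r_squared`, `species_fitted`,
#'   `n_points`.
#' @examples
#' td <- seq(0, 600, length.out = 10)
#' fit_reoxidation(td, exp(-0.005 * td), species = "fadh_rad")
#' @export
fit_reoxidation <- function(td, conc, species = c("fadh_rad", "fad_ox")) {
  species <- match.arg(species)
  if (length(td) != length(conc))
    stop("td and conc must have the same length", call. = FALSE)
  if (length(td) < 3L)
    stop("at least 3 points are required", call. = FALSE)
  if (any(td < 0) || any(diff(td) <= 0))
    stop("td must be >= 0 and strictly increasing", call. = FALSE)

  rng <- diff(range(conc))
  if (rng < 1e-12) {
    warning("concentration series is constant; reporting k1b = 0")
    return(structure(list(k1b = 0, c_o = conc[1],
                          c_ox = if (species == "fad_ox") conc[1] else NA_real_,
                          half_life = Inf, r_squared = NA_real_,
                          species_fitted = species, n_points = length(td)),
                     class = "reoxidation_fit"))
  }

  # log-linear initializer on the decaying component
  decay <- if (species == "fadh_rad") conc else max(conc) - conc + 1e-6
  pos <- decay > 1e-6
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(decay[pos]) ~ td[pos]))[[2]]
    max(-sl, 1e-6)
  } else 1e-3

  df <- data.frame(td = td, conc = conc)
  fit <- tryCatch(
    if (species == "fadh_rad") {
      minpack.lm::nlsLM(conc ~ c_o * exp(-k1b * td), data = df,
                        start = list(c_o = max(conc[1], 1e-3), k1b = k0),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(conc ~ c_ox + c_o * (1 - exp(-k1b * td)), data = df,
                        start = list(c_ox = conc[1],
                                     c_o = max(conc[length(conc)] - conc[1], 1e-3),
                                     k1b = k0),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop("reoxidation fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))

  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((conc - mean(conc))^2)
  k1b <- cf[["k1b"]]
  structure(list(k1b = k1b,
                 c_o = cf[["c_o"]],
                 c_ox = if (species == "fad_ox") cf[["c_ox"]] else NA_real_,
                 half_life = if (k1b > 0) log(2) / k1b else Inf,
                 r_squared = r2,
                 species_fitted = species,
                 n_points = length(td)),
            class = "reoxidation_fit")
}

# Expanding-bracket monotone root finder on k in [0, Inf).
# f must be monotone with f(0) on one side of 0; bracket is doubled until
# the sign changes, then uniroot polishes to `tol`.
find_rate_root <- function(f, k_init = 0.01, tol = 1e-10, max_expand = 60) {
  f0 <- f(0)
  if (abs(f0) < tol) return(0)
  hi <- k_init
  fhi <- f(hi)
  n <- 0
  while (sign(fhi) == sign(f0)) {
    hi <- hi * 2
    fhi <- f(hi)
    n <- n + 1
    if (n > max_expand)
      stop("could not bracket the rate constant: observation outside the ",
           "range achievable by the model", call. = FALSE)
  }
  stats::uniroot(f, c(0, hi), tol = tol, maxiter = 1000)$root
}

#' Invert observed concentration to the photoreduction rate k1 (two-state)
#'
#' Given a FADH° (or FADox) concentration measured at the end of a blue
#' illumination of duration `t_illum`, and the previously determined dark
#' reoxidation rate `k1b`, finds the unique `k1 >= 0` whose two-state
#' solution reproduces the observation. With `k1b = 0` and the radical
#' species this is the closed form `-log(1 - conc)/t`.
#'
#' @param conc_obs Observed normalized concentration in `[0, 1)` for
#'   `fadh_rad` (in `(0, 1]` for `fad_ox`).
#' @param species `"fadh_rad"` or `"fad_ox"`.
#' @param t_illum Illumination time (s), > 0.
#' @param k1b Dark reoxidation rate (s^-1), >= 0.
#' @return The rate constant k1 (s^-1).
#' @examples
#' infer_k1(0.5, "fadh_rad", t_illum = 20, k1b = 0) # ln(2)/20
#' @export
infer_k1 <- function(conc_obs, species = c("fadh_rad", "fad_ox"),
                     t_illum, k1b = 0) {
  species <- match.arg(species)
  if (t_illum <= 0) stop("t_illum must be > 0", call. = FALSE)
  if (k1b < 0) stop("k1b must be >= 0", call. = FALSE)
  fadh_obs <- if (species == "fadh_rad") conc_obs else 1 - conc_obs
  if (fadh_obs < 0 || fadh_obs >= 1)
    stop("observed FADH concentration must lie in [0, 1): got ",
         signif(fadh_obs, 6), call. = FALSE)
  if (fadh_obs == 0) return(0)
  if (k1b == 0)
    return(-log(1 - fadh_obs) / t_illum)
  find_rate_root(function(k1)
    two_state_concentrations(k1, k1b, t_illum)[["fadh_rad"]] - fadh_obs,
    k_init = max(k1b, 1e-3))
}

#' Invert observed FADH° to the green-light rate k2 (three-state)
#'
#' Given the FADH° concentration at the end of a blue + green
#' co-illumination of duration `t_illum`, with `k1`, `k1b`, `k2b` known,
#' finds the unique `k2 >= 0` for which the three-state simulation starting
#' from dark reproduces the observation. Green light only depletes the
#' radical, so the observed value must not exceed the `k2 = 0` prediction.
#'
#' Setting `k1b = k2b = 0` gives the reduced mode appropriate for
#' illumination times much shorter than the reoxidation timescales.
#'
#' @param fadh_obs Observed normalized FADH° in `[0, 1]`.
#' @param t_illum Illumination time (s), > 0.
#' @param k1 Blue photoreduction rate (s^-1).
#' @param k1b,k2b Dark reoxidation rates (s^-1); default 0 (neglected).
#' @param step Integrator step (s) for the forward solves; default
#'   `t_illum/2000`.
#' @param tol Slack allowed above the `k2 = 0` prediction before the
#'   observation is declared inconsistent (absorbs measurement noise).
#' @return The rate constant k2 (s^-1).
#' @export
infer_k2 <- function(fadh_obs, t_illum, k1, k1b = 0, k2b = 0,
                     step = t_illum / 2000, tol = 0.02) {
  if (t_illum <= 0) stop("t_illum must be > 0", call. = FALSE)
  if (fadh_obs < 0 || fadh_obs > 1)
    stop("fadh_obs must lie in [0, 1]", call. = FALSE)
  fadh_at <- function(k2)
    simulate_photocycle(rate_constants(k1, k2, k1b, k2b),
                        times = t_illum, step = step)$fadh_rad
  f0 <- fadh_at(0)
  if (fadh_obs > f0 + tol)
    stop("observed FADH (", signif(fadh_obs, 4), ") exceeds the k2 = 0 ",
         "prediction (", signif(f0, 4), "): data inconsistent with the ",
         "three-state model", call. = FALSE)
  if (fadh_obs >= f0) return(0)
  find_rate_root(function(k2) fadh_at(k2) - fadh_obs,
                 k_init = max(k1, 1e-3))
}

#' Through-origin dose-response fit of the photoconversion cross section
#'
#' The light-driven rate constant is proportional to the photon fluence
#' rate, `k = sigma * I`, with no intercept (no light, no photoreduction).
#' Least squares through the origin gives
#' `sigma = sum(I k) / sum(I^2)`; the goodness of fit is the uncentered
#' R^2 (`1 - SS_res / sum(k^2)`), appropriate for a no-intercept model.
#' A single point suffices for a cross-section estimate (R^2 undefined).
#'
#' @param fluence Photon fluence rates (µmol m^-2 s^-1), >= 0, not all 0.
#' @param k Rate constants (s^-1), same length.
#' @param weights Optional non-negative weights (e.g. inverse variances of
#'   the inverted rate constants). Default `NULL`: ordinary (unweighted)
#'   through-origin least squares.
#' @return List of class `"cross_section_fit"`: `sigma` (µmol^-1 m^2),
#'   `r_squared` (NA with a single point), `n_points`.
#' @examples
#' fit_cross_section(c(10, 100, 400), 1.6e-4 * c(10, 100, 400))
#' @export
fit_cross_section <- function(fluence, k, weights = NULL) {
  if (length(fluence) != length(k))
    stop("fluence and k must have the same length", call. = FALSE)
  if (length(fluence) < 1L) stop("no data", call. = FALSE)
  if (any(fluence < 0)) stop("fluence rates must be >= 0", call. = FALSE)
  if (all(fluence == 0))
    stop("all fluence rates are zero: cross section unidentifiable",
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(fluence)) else weights
  if (length(w) != length(fluence) || any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite, non-negative, and match the data length",
         call. = FALSE)
  if (all(w * fluence == 0))
    stop("no weighted information at nonzero fluence", call. = FALSE)
  sigma <- sum(w * fluence * k) / sum(w * fluence^2)
  r2 <- if (length(fluence) >= 2L) {
    ss_res <- sum(w * (k - sigma * fluence)^2)
    ss_tot <- sum(w * k^2)
    if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  } else NA_real_
  structure(list(sigma = sigma, r_squared = r2, n_points = length(fluence)),
            class = "cross_section_fit")
}

#' Quantum yield from a photoconversion cross section
#'
#' The cross section and quantum yield are related by
#' `sigma = 2.3 * eps * phi`. The cross section is carried in µmol^-1 m^2
#' (the natural partner of fluence rates in µmol m^-2 s^-1) and the
#' extinction in mol^-1 m^2, so the mol/µmol bridge (factor 1e6) is applied
#' here, in exactly one place:
#' `phi = sigma * 1e6 / (2.3 * eps)`.
#'
#' @param sigma Photoconversion cross section (µmol^-1 m^2), >= 0.
#' @param epsilon Extinction coefficient (mol^-1 m^2), > 0.
#' @return Quantum yield (dimensionless); a warning is issued if > 1, which
#'   indicates signal amplification or a unit error.
#' @examples
#' quantum_yield(1.6e-4, 509.4) # ~0.137
#' @export
quantum_yield <- function(sigma, epsilon) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("extinction coefficient must be > 0", call. = FALSE)
  if (any(sigma < 0)) stop("cross section must be >= 0", call. = FALSE)
  phi <- sigma * 1e6 / (2.3 * epsilon)
  if (any(phi > 1))
    warning("quantum yield > 1: check units or consider readout ",
            "signal amplification")
  phi
}

#' Full cross-section result for one photoconversion transition
#'
#' Bundles a fitted cross section with the derived quantum yield and the
#' extinction used.
#'
#' @param fit A `"cross_section_fit"` from [fit_cross_section()].
#' @param epsilon Extinction coefficient used (mol^-1 m^2).
#' @param transition `"ox_to_radical"` (blue, sigma1/phi1) or
#'   `"radical_to_reduced"` (green, sigma2/phi2).
#' @param species_fitted Which concentration fed the inversion.
#' @return List of class `"cross_section_result"` with fields `sigma`,
#'   `phi`, `epsilon`, `r_squared`, `n_points`, `transition`,
#'   `species_fitted`.
#' @export
cross_section_result <- function(fit, epsilon,
                                 transition = c("ox_to_radical",
                                                "radical_to_reduced"),
                                 species_fitted = "fadh_rad") {
  stopifnot(inherits(fit, "cross_section_fit"))
  transition <- match.arg(transition)
  structure(list(sigma = fit$sigma,
                 phi = quantum_yield(fit$sigma, epsilon),
                 epsilon = epsilon,
                 r_squared = fit$r_squared,
                 n_points = fit$n_points,
                 transition = transition,
                 species_fitted = species_fitted),
            class = "cross_section_result")
}

#' Average FADox-based and FADH°-based estimates into one summary row
#'
#' The analysis can be run with either redox species as input; when both are
#' available their half-lives, cross sections, and quantum yields are
#' averaged into a single condition summary (the convention used in the
#' results table).
#'
#' @param condition Condition label (e.g. `"Cry2 pH = 7.5"`).
#' @param fit_a,fit_b Two results for the same condition: either two
#'   `"reoxidation_fit"`s or two `"cross_section_result"`s.
#' @return A one-row data.frame with the averaged quantities (columns
#'   among `condition`, `tau_half_s`, `sigma_mol_m2`, `phi`).
#' @examples
#' a <- fit_cross_section(c(100, 200), 1.6e-4 * c(100, 200))
#' b <- fit_cross_section(c(100, 200), 2.8e-4 * c(100, 200))
#' average_condition_summary("Cry2 pH = 7.5",
#'                           cross_section_result(a, 509.4),
#'                           cross_section_result(b, 509.4, species_fitted = "fad_ox"))
#' @export
average_condition_summary <- function(condition, fit_a, fit_b) {
  if (!identical(class(fit_a), class(fit_b)))
    stop("the two results must be of the same type", call. = FALSE)
  if (inherits(fit_a, "reoxidation_fit")) {
    data.frame(condition = condition,
               tau_half_s = mean(c(fit_a$half_life, fit_b$half_life)),
               k1b = mean(c(fit_a$k1b, fit_b$k1b)))
  } else if (inherits(fit_a, "cross_section_result")) {
    if (!identical(fit_a$transition, fit_b$transition))
      stop("results describe different transitions", call. = FALSE)
    data.frame(condition = condition,
               transition = fit_a$transition,
               sigma_umol_m2 = mean(c(fit_a$sigma, fit_b$sigma)),
               sigma_mol_m2 = mean(c(fit_a$sigma, fit_b$sigma)) * 1e6,
               phi = mean(c(fit_a$phi, fit_b$phi)))
  } else stop("unsupported result type", call. = FALSE)
}
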