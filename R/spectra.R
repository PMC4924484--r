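# Beer-Lambert bridge between absorbance spectra (400-570 nm) and redox-state
# concentrations. Only two wavelengths carry information:
#   A(450) = eps_ox(450) [FADox] + eps_H(450) [FADH°]
#   A(560) = eps_H(560)  [FADH°]
# with the half-extinction assumption eps_H(450) = eps_H(560) = eps_ox(450)/2.
# FADH- absorbs outside this window and is recovered by conservation.

#' Extinction coefficients in vitro
#'
#' Experimentally determined oxidized-flavin extinction coefficients at
#' 450 nm for the two Arabidopsis cryptochromes, in mol^-1 m^2:
#' cry1 641.55 (6415.5 M^-1 cm^-1), cry2 509.4 (5094 M^-1 cm^-1).
#'
#' @param receptor `"cry1"` or `"cry2"`.
#' @return Extinction coefficient at 450 nm (mol^-1 m^2).
#' @examples
#' cry_extinction("cry2")
#' @export
cry_extinction <- function(receptor = c("cry1", "cry2")) {
  receptor <- match.arg(receptor)
  c(cry1 = 641.55, cry2 = 509.4)[[receptor]]
}

#' Construct an extinction-coefficient set
#'
#' Holds the extinctions the two-wavelength deconvolution relies on and the
#' optical path length. By default the radical half-extinction assumption
#' `eps_h_450 = eps_h_560 = eps_ox_450/2` is enforced.
#'
#' @param eps_ox_450 FADox extinction at 450 nm (mol^-1 m^2).
#' @param eps_h_450,eps_h_560 FADH° extinctions (mol^-1 m^2); default half of
#'   `eps_ox_450`.
#' @param path_length Optical path (cm), default 1 cm cuvette.
#' @param assume_half_extinction Assert the default relation (logical).
#' @return A list of class `"extinction_set"`.
#' @examples
#' extinction_set(cry_extinction("cry2"))
#' @export
extinction_set <- function(eps_ox_450,
                           eps_h_450 = eps_ox_450 / 2,
                           eps_h_560 = eps_ox_450 / 2,
                           path_length = 1,
                           assume_half_extinction = TRUE) {
  vals <- c(eps_ox_450, eps_h_450, eps_h_560, path_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("extinctions and path length must be positive and finite",
         call. = FALSE)
  if (assume_half_extinction &&
      (abs(eps_h_450 - eps_ox_450 / 2) > 1e-9 * eps_ox_450 ||
       abs(eps_h_560 - eps_ox_450 / 2) > 1e-9 * eps_ox_450))
    stop("half-extinction assumption requires eps_h_450 = eps_h_560 = ",
         "eps_ox_450/2; pass assume_half_extinction = FALSE to relax",
         call. = FALSE)
  structure(list(eps_ox_450 = eps_ox_450, eps_h_450 = eps_h_450,
                 eps_h_560 = eps_h_560, path_length = path_length),
            class = "extinction_set")
}

spectrum_conditions <- c("illuminated_blue", "illuminated_blue_green",
                         "dark_recovery", "dark_initial")

#' Construct one absorbance spectrum record
#'
#' @param wavelengths Strictly increasing wavelength grid (nm) within
#'   400-570.
#' @param absorbance Absorbance values (AU), same length, finite.
#' @param time Acquisition time (s): illumination time or dark-recovery time
#'   depending on `condition`.
#' @param condition One of `"illuminated_blue"`, `"illuminated_blue_green"`,
#'   `"dark_recovery"`, `"dark_initial"`.
#' @param fluence_blue,fluence_green Photon fluence rates
#'   (µmol m^-2 s^-1), >= 0; both must be 0 for dark conditions.
#' @return A list of class `"spectrum_record"`.
#' @export
spectrum_record <- function(wavelengths, absorbance, time = 0,
                            condition = "dark_initial",
                            fluence_blue = 0, fluence_green = 0) {
  condition <- match.arg(condition, spectrum_conditions)
  if (length(wavelengths) != length(absorbance))
    stop("wavelengths and absorbance must have the same length",
         call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wavelengths) < 400 || max(wavelengths) > 570)
    stop("wavelength grid must lie within 400-570 nm", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance values must be finite", call. = FALSE)
  if (fluence_blue < 0 || fluence_green < 0)
    stop("fluence rates must be >= 0", call. = FALSE)
  if (condition %in% c("dark_recovery", "dark_initial") &&
      (fluence_blue > 0 || fluence_green > 0))
    stop("dark conditions must have zero fluence rates", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance),
                 time = time, condition = condition,
                 fluence_blue = fluence_blue, fluence_green = fluence_green),
            class = "spectrum_record")
}

# Single-wavelength absorbance by nearest-neighbor lookup within +/- 2 nm.
# The measurement bands are ~20 nm wide but the deconvolution uses
# single-wavelength absorbances at 450 and 560 nm.
spectrum_absorbance_at <- function(record, wavelength, window = 2) {
  stopifnot(inherits(record, "spectrum_record"))
  i <- which.min(abs(record$wavelengths - wavelength))
  if (abs(record$wavelengths[i] - wavelength) > window)
    stop("no wavelength within ", window, " nm of ", wavelength,
         " nm on this spectrum's grid", call. = FALSE)
  record$absorbance[i]
}

#' Normalize a spectral series to the initial dark spectrum
#'
#' Divides every absorbance value by the dark record's absorbance at 450 nm,
#' so the dark spectrum has A(450) = 1 and concentrations derived by the
#' two-wavelength rule are on the normalized (sum-to-one) scale.
#'
#' @param series A list of [spectrum_record()]s.
#' @param dark A [spectrum_record()] with condition `"dark_initial"` and
#'   positive absorbance at 450 nm.
#' @return The series with normalized absorbances (same structure).
#' @export
normalize_to_dark <- function(series, dark) {
  stopifnot(inherits(dark, "spectrum_record"))
  if (dark$condition != "dark_initial")
    stop("reference record must have condition 'dark_initial'",
         call. = FALSE)
  a450 <- spectrum_absorbance_at(dark, 450)
  if (a450 <= 0)
    stop("dark absorbance at 450 nm must be > 0 (got ", a450, ")",
         call. = FALSE)
  single <- inherits(series, "spectrum_record")
  if (single) series <- list(series)
  out <- lapply(series, function(rec) {
    stopifnot(inherits(rec, "spectrum_record"))
    rec$absorbance <- rec$absorbance / a450
    rec
  })
  if (single) out[[1]] else out
}

#' Redox-state concentrations from normalized absorbance
#'
#' Applies the two-wavelength deconvolution under the half-extinction
#' assumption: `fad_ox = A(450) - A(560)`, `fadh_rad = 2 A(560)`, and
#' `fadh_minus` by conservation (it does not absorb in 400-570 nm).
#'
#' Components are allowed to stray into `[-tol, 1 + tol]` to absorb
#' measurement noise and are then clamped to `[0, 1]` (renormalized to sum
#' to 1); grosser violations raise an error.
#'
#' @param a450,a560 Normalized absorbance at 450 and 560 nm.
#' @param tol Physicality tolerance, default 0.02.
#' @param label Optional label used in error messages (e.g. which spectrum).
#' @return A [state_vector()].
#' @examples
#' absorbance_to_concentrations(0.5, 0.25)
#' @export
absorbance_to_concentrations <- function(a450, a560, tol = 0.02,
                                         label = NULL) {
  fad_ox <- a450 - a560
  fadh_rad <- 2 * a560
  fadh_minus <- 1 - fad_ox - fadh_rad
  comps <- c(fad_ox, fadh_rad, fadh_minus)
  if (any(comps < -tol) || any(comps > 1 + tol))
    stop("unphysical concentrations",
         if (!is.null(label)) paste0(" in ", label),
         ": (", paste(signif(comps, 4), collapse = ", "),
         ") outside [", -tol, ", ", 1 + tol, "]", call. = FALSE)
  comps <- pmin(pmax(comps, 0), 1)
  comps <- comps / sum(comps)
  state_vector(comps[1], comps[2], comps[3])
}

#' Normalized absorbance from redox-state concentrations
#'
#' Inverse of [absorbance_to_concentrations()] under the half-extinction
#' assumption: `a450 = fad_ox + fadh_rad/2`, `a560 = fadh_rad/2`.
#'
#' @param state A [state_vector()].
#' @return Named numeric vector `(a450, a560)` in normalized AU.
#' @export
concentrations_to_absorbance <- function(state) {
  s <- as_state_vector(state)
  c(a450 = s[["fad_ox"]] + s[["fadh_rad"]] / 2,
    a560 = s[["fadh_rad"]] / 2)
}

#' Molar cryptochrome concentration from dark absorbance
#'
#' In the dark all flavin is oxidized, so
#' `A(450, 0) = eps_ox(450) * [protein] * d` gives the sample concentration
#' directly.
#'
#' @param a450_dark Raw (unnormalized) absorbance at 450 nm of the dark
#'   sample (AU), > 0.
#' @param eps An [extinction_set()] (extinctions in mol^-1 m^2, path in cm).
#' @return Molar concentration (M).
#' @examples
#' initial_molar_concentration(0.64155, extinction_set(641.55)) # 1e-4 M
#' @export
initial_molar_concentration <- function(a450_dark, eps) {
  stopifnot(inherits(eps, "extinction_set"))
  if (!is.finite(a450_dark) || a450_dark <= 0)
    stop("dark absorbance at 450 nm must be > 0", call. = FALSE)
  eps_M_cm <- eps$eps_ox_450 * 10 # mol^-1 m^2 -> M^-1 cm^-1
  a450_dark / (eps_M_cm * eps$path_length)
}

#' Convert extinction coefficient units
#'
#' `1 M^-1 cm^-1 = 0.1 mol^-1 m^2`, so e.g. 6415.5 M^-1 cm^-1 = 641.55
#' mol^-1 m^2 (cry1) and 5094 = 509.4 (cry2). The package stores mol^-1 m^2
#' internally and accepts M^-1 cm^-1 at I/O.
#'
#' @param eps_M_cm Extinction in M^-1 cm^-1, > 0.
#' @return Extinction in mol^-1 m^2.
#' @export
convert_epsilon_units <- function(eps_M_cm) {
  if (any(!is.finite(eps_M_cm)) || any(eps_M_cm <= 0))
    stop("extinction coefficient must be > 0", call. = FALSE)
  eps_M_cm / 10
}

#' Concentration time course from a normalized spectral series
#'
#' Convenience wrapper: extracts A(450) and A(560) from each record and
#' applies [absorbance_to_concentrations()].
#'
#' @param series List of normalized [spectrum_record()]s.
#' @param tol Physicality tolerance passed through.
#' @return Data frame with columns `time`, `condition`, `fad_ox`,
#'   `fadh_rad`, `fadh_minus`.
#' @export
series_concentrations <- function(series, tol = 0.02) {
  rows <- lapply(seq_along(series), function(i) {
    rec <- series[[i]]
    s <- absorbance_to_concentrations(
      spectrum_absorbance_at(rec, 450), spectrum_absorbance_at(rec, 560),
      tol = tol, label = paste0("spectrum ", i, " (t=", rec$time, " s)"))
    data.frame(time = rec$time, condition = rec$condition,
               fad_ox = s[["fad_ox"]], fadh_rad = s[["fadh_rad"]],
               fadh_minus = s[["fadh_minus"]])
  })
  do.call(rbind, rows)
}
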