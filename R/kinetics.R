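# Three-state photocycle kinetics: FADox <-> FADH° <-> FADH-
#
# d[FADox]/dt  = -k1 [FADox] + k1b [FADH°] + k2b [FADH-]
# d[FADH°]/dt  =  k1 [FADox] - (k2 + k1b) [FADH°]
# d[FADH-]/dt  =  k2 [FADH°] - k2b [FADH-]
#
# k1, k2 are light-driven forward rates; k1b, k2b are light-independent
# reoxidation rates. Concentrations are normalized so the three states sum
# to 1.

#' Construct a photocycle state vector
#'
#' Normalized concentrations of the three flavin redox species of the
#' cryptochrome chromophore: oxidized flavin (FADox), the neutral radical
#' (FADH°, the putative signaling state), and fully reduced flavin (FADH-).
#' Components must lie in `[0, 1]` and sum to 1.
#'
#' @param fad_ox,fadh_rad,fadh_minus Normalized concentrations
#'   (dimensionless).
#' @return A named numeric vector of class `"state_vector"`.
#' @examples
#' state_vector(1, 0, 0)        # dark resting state
#' state_vector(0.25, 0.5, 0.25)
#' @export
state_vector <- function(fad_ox, fadh_rad, fadh_minus) {
  s <- c(fad_ox = fad_ox, fadh_rad = fadh_rad, fadh_minus = fadh_minus)
  class(s) <- "state_vector"
  validate_state_vector(s)
  s
}

validate_state_vector <- function(s, tol = 1e-9) {
  if (!is.numeric(s) || length(s) != 3L || anyNA(s) || any(!is.finite(s)))
    stop("state vector must be three finite numeric concentrations",
         call. = FALSE)
  if (any(s < -tol) || any(s > 1 + tol))
    stop("state concentrations must lie in [0, 1]; got (",
         paste(signif(unclass(s), 6), collapse = ", "), ")", call. = FALSE)
  if (abs(sum(s) - 1) > tol)
    stop("state concentrations must sum to 1 (got ",
         format(sum(s), digits = 12), ")", call. = FALSE)
  invisible(s)
}

#' Construct the four photocycle rate constants
#'
#' @param k1 Blue-light photoreduction rate FADox -> FADH° (s^-1).
#' @param k2 Green/blue-light photoreduction rate FADH° -> FADH- (s^-1).
#' @param k1b Dark reoxidation rate FADH° -> FADox (s^-1).
#' @param k2b Dark reoxidation rate FADH- -> FADox (s^-1).
#' @return A named numeric vector of class `"rate_constants"`.
#' @examples
#' rate_constants(k1 = 0.016, k2 = 0.008, k1b = 0.003, k2b = 0.011)
#' @export
rate_constants <- function(k1 = 0, k2 = 0, k1b = 0, k2b = 0) {
  r <- c(k1 = k1, k2 = k2, k1b = k1b, k2b = k2b)
  if (!is.numeric(r) || length(r) != 4L || anyNA(r) || any(!is.finite(r)))
    stop("rate constants must be four finite numerics", call. = FALSE)
  if (any(r < 0))
    stop("rate constants must be >= 0", call. = FALSE)
  class(r) <- "rate_constants"
  r
}

as_rate_constants <- function(rates) {
  if (inherits(rates, "rate_constants")) return(rates)
  rates <- unlist(rates)
  if (is.null(names(rates)) || !all(c("k1", "k2", "k1b", "k2b") %in% names(rates)))
    stop("rates must be a rate_constants object or a named vector/list ",
         "with k1, k2, k1b, k2b", call. = FALSE)
  rate_constants(rates[["k1"]], rates[["k2"]], rates[["k1b"]], rates[["k2b"]])
}

as_state_vector <- function(state) {
  if (inherits(state, "state_vector")) {
    validate_state_vector(state)
    return(state)
  }
  state <- unlist(state)
  if (length(state) != 3L)
    stop("state must have three components", call. = FALSE)
  state_vector(state[[1]], state[[2]], state[[3]])
}

# System matrix A of the linear ODE dx/dt = A x
photocycle_matrix <- function(rates) {
  r <- as_rate_constants(rates)
  matrix(c(-r[["k1"]],             r[["k1b"]], r[["k2b"]],
            r[["k1"]], -(r[["k2"]] + r[["k1b"]]),        0,
                    0,              r[["k2"]], -r[["k2b"]]),
         nrow = 3, byrow = TRUE)
}

#' Time derivative of the photocycle state
#'
#' Evaluates the right-hand side of the coupled first-order kinetic system
#' for the three flavin redox states. The three derivative components sum to
#' zero (total concentration is conserved).
#'
#' @param state A [state_vector()].
#' @param rates A [rate_constants()].
#' @return Named numeric vector `(d[FADox]/dt, d[FADH°]/dt, d[FADH-]/dt)`
#'   in s^-1.
#' @examples
#' photocycle_derivative(state_vector(1, 0, 0),
#'                       rate_constants(k1 = 0.01))
#' @export
photocycle_derivative <- function(state, rates) {
  s <- as_state_vector(state)
  r <- as_rate_constants(rates)
  d <- drop(photocycle_matrix(r) %*% unclass(s))
  names(d) <- c("fad_ox", "fadh_rad", "fadh_minus")
  d
}

# One fixed-step classical RK4 propagator for the linear system dx/dt = A x.
# For linear f, the classical RK4 step x + h/6 (f1 + 2 f2 + 2 f3 + f4)
# collapses exactly to the degree-4 Taylor polynomial of expm(h A):
#   M = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24
# so advancing n steps is M^n, computed by repeated squaring.
rk4_step_matrix <- function(A, h) {
  hA <- h * A
  I3 <- diag(3)
  I3 + hA + hA %*% hA / 2 + hA %*% hA %*% hA / 6 +
    hA %*% hA %*% hA %*% hA / 24
}

mat_pow <- function(M, n) {
  stopifnot(n >= 0, n == round(n))
  P <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) P <- P %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  P
}

#' Simulate the three-state photocycle
#'
#' Integrates the linear kinetic system with a classical fixed-step
#' fourth-order Runge-Kutta scheme. Within each output interval the step is
#' shrunk, if needed, to divide the interval exactly, so output times are hit
#' without interpolation.
#'
#' @param rates A [rate_constants()].
#' @param initial Initial [state_vector()]; defaults to the dark resting
#'   state (all flavin oxidized).
#' @param times Strictly increasing output times (s), first >= 0.
#' @param step Integrator step (s), > 0. Default 0.01 s resolves the
#'   photocycle rates (<= 0.1 s^-1) far below their timescales.
#' @return A `data.frame` of class `"photocycle_trajectory"` with columns
#'   `time`, `fad_ox`, `fadh_rad`, `fadh_minus`.
#' @examples
#' simulate_photocycle(rate_constants(k1 = 0.01, k1b = 0.003),
#'                     times = c(0, 10, 100))
#' @export
simulate_photocycle <- function(rates, initial = state_vector(1, 0, 0),
                                times, step = 0.01) {
  r <- as_rate_constants(rates)
  x0 <- unclass(as_state_vector(initial))
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    stop("times must be numeric and non-missing", call. = FALSE)
  if (times[1] < 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing with first time >= 0",
         call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number", call. = FALSE)

  A <- photocycle_matrix(r)
  grid <- if (times[1] > 0) c(0, times) else times
  out <- matrix(NA_real_, nrow = length(grid), ncol = 3)
  x <- x0
  out[1, ] <- x
  if (length(grid) > 1L) {
    for (i in seq_len(length(grid) - 1L)) {
      dt <- grid[i + 1L] - grid[i]
      n <- max(1L, ceiling(dt / step))
      h <- dt / n
      x <- drop(mat_pow(rk4_step_matrix(A, h), n) %*% x)
      out[i + 1L, ] <- x
    }
  }
  if (times[1] > 0) out <- out[-1L, , drop = FALSE]
  traj <- data.frame(time = times, fad_ox = out[, 1], fadh_rad = out[, 2],
                     fadh_minus = out[, 3])
  class(traj) <- c("photocycle_trajectory", "data.frame")
  traj
}

#' Two-state (FADox/FADH°) concentrations under blue light
#'
#' Closed-form solution of the abbreviated photocycle in which FADH-
#' accumulation is neglected, starting from fully oxidized flavin:
#' `fadh_rad(t) = k1/(k1+k1b) * (1 - exp(-(k1+k1b) t))`,
#' `fad_ox(t) = 1 - fadh_rad(t)`.
#'
#' @param k1 Photoreduction rate (s^-1).
#' @param k1b Dark reoxidation rate (s^-1).
#' @param t Illumination time (s), >= 0.
#' @return Named numeric vector `(fad_ox, fadh_rad)`.
#' @examples
#' two_state_concentrations(k1 = 0.01, k1b = 0.003, t = 100)
#' @export
two_state_concentrations <- function(k1, k1b, t) {
  if (any(c(k1, k1b) < 0)) stop("rates must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("illumination time must be >= 0", call. = FALSE)
  ktot <- k1 + k1b
  fadh <- if (ktot == 0) rep(0, length(t)) else (k1 / ktot) * (1 - exp(-ktot * t))
  if (length(t) == 1L) c(fad_ox = 1 - fadh, fadh_rad = fadh)
  else data.frame(t = t, fad_ox = 1 - fadh, fadh_rad = fadh)
}

#' Parameters of a dark-reoxidation decay curve
#'
#' @param c_ox Initial FADox concentration at dark time zero.
#' @param c_o Initial FADH° concentration at dark time zero.
#' @param k1b Reoxidation rate (s^-1).
#' @return A list of class `"reoxidation_curve_params"`.
#' @export
reoxidation_curve_params <- function(c_ox, c_o, k1b) {
  if (c_ox < 0 || c_o < 0 || c_ox + c_o > 1 + 1e-9)
    stop("initial concentrations must be >= 0 with c_ox + c_o <= 1",
         call. = FALSE)
  if (k1b < 0) stop("k1b must be >= 0", call. = FALSE)
  structure(list(c_ox = c_ox, c_o = c_o, k1b = k1b),
            class = "reoxidation_curve_params")
}

#' Dark reoxidation of the FADH° radical
#'
#' First-order return of the radical to oxidized flavin in darkness:
#' `fadh_rad(td) = c_o exp(-k1b td)` and
#' `fad_ox(td) = c_ox + c_o (1 - exp(-k1b td))`, where `c_ox` and `c_o` are
#' the concentrations when the sample is placed in darkness.
#'
#' @param params A [reoxidation_curve_params()].
#' @param td Dark time(s) (s), >= 0.
#' @return If `td` has length 1, a named vector `(fad_ox, fadh_rad)`;
#'   otherwise a data.frame with columns `td`, `fad_ox`, `fadh_rad`.
#' @examples
#' reoxidation_decay(reoxidation_curve_params(0, 1, 0.003), td = 231)
#' @export
reoxidation_decay <- function(params, td) {
  stopifnot(inherits(params, "reoxidation_curve_params"))
  if (any(td < 0)) stop("dark time must be >= 0", call. = FALSE)
  e <- exp(-params$k1b * td)
  fadh <- params$c_o * e
  fox <- params$c_ox + params$c_o * (1 - e)
  if (length(td) == 1L) c(fad_ox = fox, fadh_rad = fadh)
  else data.frame(td = td, fad_ox = fox, fadh_rad = fadh)
}

#' Half-life of a first-order reaction
#'
#' @param k First-order rate constant (s^-1), > 0.
#' @return Half-life `ln(2)/k` in seconds.
#' @examples
#' half_life(0.003) # ~231 s
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("rate constant must be > 0", call. = FALSE)
  log(2) / k
}

#' Steady-state redox distribution under constant illumination
#'
#' Solves the kinetic system with all derivatives set to zero. Under
#' constant light the equilibrium populations are set by the balance of the
#' four rates: `fadh_rad : fad_ox = k1 : (k2 + k1b)` and
#' `fadh_minus = (k2/k2b) fadh_rad` (when `k2b > 0`).
#'
#' Degenerate configurations in which the steady state is not unique (for
#' example all rates zero, or a reduced state that can be populated but never
#' drained) raise an error rather than returning an arbitrary state.
#'
#' @param rates A [rate_constants()].
#' @return A [state_vector()].
#' @examples
#' steady_state(rate_constants(k1 = 0.003, k1b = 0.003))
#' @export
steady_state <- function(rates) {
  r <- as_rate_constants(rates)
  k1 <- r[["k1"]]; k2 <- r[["k2"]]; k1b <- r[["k1b"]]; k2b <- r[["k2b"]]
  if (all(unclass(r) == 0))
    stop("all rates are zero: every state is stationary", call. = FALSE)
  if (k1 > 0 && k1b == 0)
    stop("degenerate steady state: reduced flavin cannot return to FADox ",
         "(k1 > 0 with k1b = 0)", call. = FALSE)
  if (k2 > 0 && k2b == 0)
    stop("degenerate steady state: FADH- absorbs all concentration ",
         "(k2 > 0 with k2b = 0)", call. = FALSE)
  if (k1 == 0) return(state_vector(1, 0, 0)) # dark: everything reoxidizes
  # fadh_rad = h; fad_ox = (k2 + k1b) h / k1; fadh_minus = k2 h / k2b
  ox_h <- (k2 + k1b) / k1
  hm_h <- if (k2 == 0) 0 else k2 / k2b
  h <- 1 / (1 + ox_h + hm_h)
  state_vector(ox_h * h, h, hm_h * h)
}
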