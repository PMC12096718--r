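# Macro-constants of the disposition function. For a unit impulse into the
# central compartment the concentration is (1/V1) (A e^{-alpha t} + B e^{-beta t})
# with A + B = 1; the one-compartment limit (Q = 0) has A = 1, beta absent.
.macro_constants <- function(p) {
  if (p$Q == 0) {
    list(alpha = p$k10, beta = NA_real_, A = 1, B = 0)
  } else {
    s <- p$k10 + p$k12 + p$k21
    d <- sqrt(s^2 - 4 * p$k10 * p$k21)
    alpha <- (s + d) / 2
    beta <- (s - d) / 2
    list(alpha = alpha, beta = beta,
         A = (alpha - p$k21) / (alpha - beta),
         B = (p$k21 - beta) / (alpha - beta))
  }
}

# contribution of one exponential mode to a constant-rate infusion response:
# during infusion (elapsed tau <= T):  (1 - e^{-l tau}) / l
# after the end (tau > T):             (1 - e^{-l T}) e^{-l (tau - T)} / l
.mode_response <- function(lambda, tau, Tdur) {
  out <- numeric(length(tau))
  on <- tau > 0 & tau <= Tdur
  off <- tau > Tdur
  out[on] <- (1 - exp(-lambda * tau[on])) / lambda
  out[off] <- (1 - exp(-lambda * Tdur)) * exp(-lambda * (tau[off] - Tdur)) /
    lambda
  out
}

#' Total plasma concentration under a piecewise constant-rate regimen
#'
#' Closed-form biexponential superposition over all infusion events of a
#' two-compartment model (central concentration = central amount / V1). The
#' one-compartment limit `Q = 0` is handled exactly.
#'
#' @param p An `fd_params`.
#' @param regimen An `fd_regimen`.
#' @param t Time(s) in hours (>= 0), vectorised.
#' @return Concentration(s) in mg/L.
#' @export
#' @examples
#' p <- structural_params(CL = 10, V1 = 20)  # one-compartment
#' r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
#' concentration_at(p, r, 0.5)  # end of loading dose
concentration_at <- function(p, regimen, t) {
  stopifnot(inherits(p, "fd_params"), inherits(regimen, "fd_regimen"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  mc <- .macro_constants(p)
  conc <- numeric(length(t))
  ev <- regimen$events
  for (i in seq_len(nrow(ev))) {
    tau <- t - ev$start[i]
    contrib <- mc$A * .mode_response(mc$alpha, tau, ev$duration[i])
    if (mc$B != 0)
      contrib <- contrib + mc$B * .mode_response(mc$beta, tau, ev$duration[i])
    conc <- conc + ev$rate[i] / p$V1 * contrib
  }
  conc
}

#' Dense concentration-time profile
#'
#' Evaluates the profile on a regular grid over `[0, horizon]` augmented with
#' all infusion start/end knots (included exactly).
#'
#' @param p An `fd_params`.
#' @param regimen An `fd_regimen`.
#' @param grid_step Hours (> 0), default 0.05.
#' @return An `fd_profile`: data frame with columns `time`, `conc`.
#' @export
simulate_profile <- function(p, regimen, grid_step = 0.05) {
  stopifnot(grid_step > 0)
  knots <- with(regimen$events, c(start, start + duration))
  times <- sort(unique(c(seq(0, regimen$horizon, by = grid_step),
                         regimen$horizon,
                         knots[knots <= regimen$horizon])))
  structure(data.frame(time = times,
                       conc = concentration_at(p, regimen, times)),
            class = c("fd_profile", "data.frame"))
}

#' Terminal half-life of a two-compartment system
#'
#' ln(2) / beta, where beta is the smaller root of
#' lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0; with `Q = 0` this
#' reduces to the one-compartment `ln(2) * V1 / CL`.
#'
#' @param p An `fd_params`.
#' @return Hours.
#' @export
terminal_half_life <- function(p) {
  stopifnot(inherits(p, "fd_params"))
  mc <- .macro_constants(p)
  lambda <- if (p$Q == 0) mc$alpha else mc$beta
  log(2) / lambda
}

#' Terminal half-life by log-linear regression on the simulated tail
#'
#' Cross-check for [terminal_half_life()]: fits log-concentration against
#' time over the late decay phase of a single-dose profile.
#'
#' @param p An `fd_params`.
#' @param t_start,t_end Regression window in hours after a single 1000 mg /
#'   0.5 h infusion; defaults cover the terminal phase.
#' @return Hours.
#' @export
terminal_half_life_regression <- function(p, t_start = 5 * terminal_half_life(p),
                                          t_end = 8 * terminal_half_life(p)) {
  r <- regimen_from_events("meropenem", start = 0, duration = 0.5,
                           amount = 1000, tau = t_end + 1,
                           horizon = t_end + 1)
  tt <- seq(t_start, t_end, length.out = 50)
  cc <- concentration_at(p, r, tt)
  fit <- stats::lm(log(cc) ~ tt)
  -log(2) / unname(stats::coef(fit)[2L])
}
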