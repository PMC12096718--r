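#' MIC-based exposure target
#'
#' Converts a free-drug MIC target into a total-concentration threshold:
#' `multiplier * mic / unbound_fraction`. The package defaults follow
#' EUCAST epidemiological cut-offs for P. aeruginosa: MIC 2 mg/L for
#' meropenem (protein binding disregarded, fu = 1) and 16 mg/L for
#' piperacillin with an assumed 20% binding (fu = 0.8), giving a 20 mg/L
#' total target.
#'
#' @param mic Minimum inhibitory concentration, mg/L (>= 0).
#' @param unbound_fraction Free fraction in (0, 1].
#' @param multiplier 1 (plain MIC target) or 4 (4xMIC).
#' @return An `fd_target` with the derived `total_threshold`.
#' @export
#' @examples
#' mic_target(16, unbound_fraction = 0.8)$total_threshold  # 20 mg/L
mic_target <- function(mic, unbound_fraction = 1, multiplier = 1) {
  if (unbound_fraction <= 0 || unbound_fraction > 1)
    stop("unbound_fraction must be in (0, 1]", call. = FALSE)
  stopifnot(mic >= 0, multiplier > 0)
  structure(list(mic = mic, unbound_fraction = unbound_fraction,
                 multiplier = multiplier,
                 total_threshold = multiplier * mic / unbound_fraction),
            class = "fd_target")
}

#' Default MIC target per drug
#'
#' @param drug Drug label.
#' @param multiplier 1 or 4.
#' @return An `fd_target`.
#' @export
default_target <- function(drug = c("meropenem", "piperacillin"),
                           multiplier = 1) {
  drug <- match.arg(drug)
  if (drug == "meropenem") mic_target(2, 1.0, multiplier)
  else mic_target(16, 0.8, multiplier)
}

#' Total-concentration threshold of a target
#'
#' @param target An `fd_target`.
#' @return mg/L.
#' @export
total_threshold <- function(target) target$total_threshold

# measure of {t in [t0, t1] : C(t) > thr} for a piecewise-smooth profile.
# Crossings are bracketed on a fine grid within each inter-knot segment and
# refined with uniroot; sub-intervals are classified at their midpoint.
.time_above <- function(p, regimen, thr, t0, t1, substep = 0.02,
                        tol = 1e-7) {
  if (t1 <= t0) return(0)
  if (thr <= 0) {
    # concentration is 0 exactly at t = 0 and positive afterwards
    return(t1 - max(t0, 0))
  }
  knots <- with(regimen$events, sort(unique(c(start, start + duration))))
  knots <- knots[knots > t0 & knots < t1]
  seg <- sort(unique(c(t0, knots, t1)))
  cross <- numeric(0)
  f <- function(t) concentration_at(p, regimen, t) - thr
  for (i in seq_len(length(seg) - 1L)) {
    a <- seg[i]; b <- seg[i + 1L]
    grid <- seq(a, b, length.out = max(3L, ceiling((b - a) / substep) + 1L))
    fv <- f(grid)
    sgn <- sign(fv)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (j in idx) {
      r <- stats::uniroot(f, c(grid[j], grid[j + 1L]), tol = tol)
      cross <- c(cross, r$root)
    }
    # grid points lying exactly on the threshold are crossings too
    cross <- c(cross, grid[fv == 0])
  }
  pts <- sort(unique(c(t0, cross, t1)))
  above <- 0
  for (i in seq_len(length(pts) - 1L)) {
    mid <- (pts[i] + pts[i + 1L]) / 2
    if (f(mid) > 0) above <- above + (pts[i + 1L] - pts[i])
  }
  above
}

#' Percent of time above the target threshold
#'
#' Fraction (as a percentage) of the evaluation window during which the
#' total concentration exceeds the fu-adjusted total threshold — identical
#' to the free concentration exceeding `multiplier * MIC` under constant
#' protein binding. The first dosing interval is `[0, loading_duration +
#' tau]`; the 24 h window is `[0, 24]` under an unchanged regimen.
#'
#' @param p An `fd_params`.
#' @param regimen An `fd_regimen`.
#' @param target An `fd_target`.
#' @param window `"first_interval"` or `"first_24h"`.
#' @return Percent in [0, 100].
#' @export
ft_above_target <- function(p, regimen, target,
                            window = c("first_interval", "first_24h")) {
  window <- match.arg(window)
  t1 <- switch(window, first_interval = interval_end(regimen),
               first_24h = 24)
  if (t1 > regimen$horizon)
    stop("regimen horizon shorter than the evaluation window", call. = FALSE)
  100 * .time_above(p, regimen, total_threshold(target), 0, t1) / t1
}

#' Model-predicted trough at the exact end of the first dosing interval
#'
#' Concentration at `loading_duration + tau`. The second maintenance
#' infusion starts at exactly this time but contributes nothing at its own
#' start, so the value is the pre-dose trough.
#'
#' @param p An `fd_params`.
#' @param regimen An `fd_regimen`.
#' @return mg/L.
#' @export
predicted_trough <- function(p, regimen) {
  concentration_at(p, regimen, interval_end(regimen))
}

#' Observed-trough target attainment
#'
#' A trough strictly above the total threshold is considered equivalent to
#' 100% fT>MIC over the interval.
#'
#' @param cmin_observed mg/L (> 0).
#' @param target An `fd_target`.
#' @return Logical.
#' @export
attained_observed <- function(cmin_observed, target) {
  stopifnot(cmin_observed > 0)
  cmin_observed > total_threshold(target)
}

#' Dose-normalised trough-to-peak ratio
#'
#' Cmin and Cmax are normalised to a common reference dose before forming
#' the ratio: Cmax reflects the loading dose, Cmin the maintenance dose.
#' With equal dose amounts this reduces to `cmin / cmax`.
#'
#' @param cmax,cmin mg/L (> 0).
#' @param loading_amount,maintenance_amount mg (> 0).
#' @param reference_amount mg, e.g. 1000 (meropenem) or 4000 (piperacillin).
#' @return Unitless ratio.
#' @export
cmin_cmax_ratio <- function(cmax, cmin, loading_amount = reference_amount,
                            maintenance_amount = reference_amount,
                            reference_amount = 1000) {
  if (any(c(cmax, cmin, loading_amount, maintenance_amount,
            reference_amount) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  (cmin * reference_amount / maintenance_amount) /
    (cmax * reference_amount / loading_amount)
}

#' Per-patient exposure summary
#'
#' Assembles the exposure endpoints from a converged individual fit, the
#' observations, the regimen and the MIC target: observed Cmax/Cmin,
#' model-predicted trough at the exact interval end, %fT>MIC over the first
#' interval and first 24 h (also against 4xMIC), attainment flags,
#' dose-normalised Cmin/Cmax ratio and terminal half-life. Flags
#' observed-vs-predicted attainment discordance (typically from mistimed
#' trough sampling).
#'
#' @param fit An `fd_fit` (converged).
#' @param obs An `fd_obs`.
#' @param regimen An `fd_regimen`.
#' @param target An `fd_target` (multiplier 1).
#' @param reference_amount Dose-normalisation reference, mg; defaults to
#'   1000 for meropenem and 4000 for piperacillin.
#' @return An `fd_exposure` list.
#' @export
exposure_summary <- function(fit, obs, regimen, target,
                             reference_amount = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (is.null(reference_amount))
    reference_amount <- if (regimen$drug == "meropenem") 1000 else 4000
  p <- fit$individual
  thr <- total_threshold(target)
  target4 <- mic_target(target$mic, target$unbound_fraction,
                        4 * target$multiplier)

  cmax_row <- obs[obs$role == "post_loading_cmax" & !obs$blq, , drop = FALSE]
  trough_row <- obs[obs$role == "trough" & !obs$blq, , drop = FALSE]
  cmax_obs <- if (nrow(cmax_row)) cmax_row$conc[1L] else NA_real_
  cmin_obs <- if (nrow(trough_row)) trough_row$conc[1L] else NA_real_
  cmin_time <- if (nrow(trough_row)) trough_row$time[1L] else NA_real_
  if (!nrow(trough_row))
    message("patient without usable trough: observed attainment unavailable, ",
            "reporting model-predicted attainment only")

  cmin_pred <- predicted_trough(p, regimen)
  ft_int <- ft_above_target(p, regimen, target, "first_interval")
  ft_24 <- ft_above_target(p, regimen, target, "first_24h")
  ft4_int <- ft_above_target(p, regimen, target4, "first_interval")
  ft4_24 <- ft_above_target(p, regimen, target4, "first_24h")

  att_obs <- if (is.na(cmin_obs)) NA else attained_observed(cmin_obs, target)
  att_pred <- cmin_pred > thr
  ratio <- if (!is.na(cmax_obs) && !is.na(cmin_obs))
    cmin_cmax_ratio(cmax_obs, cmin_obs, regimen$loading_amount,
                    regimen$maintenance_amount, reference_amount)
  else NA_real_

  structure(list(
    cmax_observed = cmax_obs,
    cmin_observed = cmin_obs,
    cmin_observed_time = cmin_time,
    cmin_predicted_at_tau = cmin_pred,
    ft_above_interval = ft_int,
    ft_above_24h = ft_24,
    ft_above_4xmic_interval = ft4_int,
    ft_above_4xmic_24h = ft4_24,
    attained_100 = att_pred,
    attained_100_observed = att_obs,
    attained_50 = ft_int >= 50,
    discordant = !is.na(att_obs) && att_obs != att_pred,
    cmin_cmax_ratio = ratio,
    terminal_half_life = terminal_half_life(p)),
    class = "fd_exposure")
}

#' @export
print.fd_exposure <- function(x, ...) {
  cat(sprintf(paste0("<exposure> Cmax obs %.3g, Cmin obs %.3g (t=%.2f h), ",
                     "Cmin pred %.3g mg/L\n  fT>MIC %.1f%% (interval), ",
                     "%.1f%% (24 h); attained(pred) %s%s; ratio %.3g; ",
                     "t1/2 %.2f h\n"),
              x$cmax_observed, x$cmin_observed, x$cmin_observed_time,
              x$cmin_predicted_at_tau, x$ft_above_interval, x$ft_above_24h,
              x$attained_100,
              if (x$discordant) " [discordant with observed]" else "",
              x$cmin_cmax_ratio, x$terminal_half_life))
  invisible(x)
}
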