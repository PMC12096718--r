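#' Dosing regimen: loading dose plus extended maintenance infusions
#'
#' Represents the study regimen: a loading dose infused over
#' `loading_duration` hours starting at time 0, immediately followed by
#' extended maintenance infusions of `maintenance_duration` hours starting at
#' `loading_duration + k * tau` for k = 0, 1, ... within `horizon`.
#'
#' @param drug `"meropenem"` or `"piperacillin"`.
#' @param loading_amount mg (> 0).
#' @param maintenance_amount mg (> 0).
#' @param tau Maintenance dosing interval in hours (typically 6, 8 or 12).
#' @param loading_duration Hours, default 0.5.
#' @param maintenance_duration Hours, default 3.
#' @param horizon Hours simulated, default 24.
#' @return An `fd_regimen` object; `$events` is a data frame with columns
#'   `start`, `duration`, `amount`, `rate` (mg/h).
#' @export
#' @examples
#' dosing_regimen("meropenem", 1000, 1000, tau = 8)
dosing_regimen <- function(drug, loading_amount, maintenance_amount, tau,
                           loading_duration = 0.5, maintenance_duration = 3,
                           horizon = 24) {
  drug <- match.arg(drug, c("meropenem", "piperacillin"))
  loading_amount <- as.numeric(loading_amount)
  maintenance_amount <- as.numeric(maintenance_amount)
  tau <- as.numeric(tau)
  stopifnot(loading_amount > 0, maintenance_amount > 0, tau > 0,
            loading_duration > 0, maintenance_duration > 0,
            maintenance_duration <= tau, horizon > 0)
  starts <- loading_duration + tau * (0:ceiling(horizon / tau))
  starts <- starts[starts < horizon]
  events <- data.frame(
    start = c(0, starts),
    duration = c(loading_duration, rep(maintenance_duration, length(starts))),
    amount = c(loading_amount, rep(maintenance_amount, length(starts))))
  events$rate <- events$amount / events$duration
  structure(list(drug = drug, loading_amount = loading_amount,
                 maintenance_amount = maintenance_amount, tau = tau,
                 loading_duration = loading_duration,
                 maintenance_duration = maintenance_duration,
                 horizon = horizon, events = events),
            class = "fd_regimen")
}

#' End of the first dosing interval
#'
#' The first dosing interval runs from the start of the loading dose to the
#' start of the second maintenance infusion, i.e. `loading_duration + tau`
#' (the interval clock is anchored at the start of the first extended
#' infusion).
#'
#' @param regimen An `fd_regimen`.
#' @return Time in hours.
#' @export
interval_end <- function(regimen) {
  stopifnot(inherits(regimen, "fd_regimen"))
  regimen$loading_duration + regimen$tau
}

#' Regimen from explicit infusion events
#'
#' Lower-level constructor used by the event-table reader; events need not
#' follow the loading + q-tau template.
#'
#' @param drug Drug label.
#' @param start,duration,amount Parallel numeric vectors (hours, hours, mg).
#' @param tau Dosing interval to associate for interval-based metrics.
#' @param horizon Hours.
#' @return An `fd_regimen`.
#' @export
regimen_from_events <- function(drug, start, duration, amount, tau,
                                horizon = 24) {
  drug <- match.arg(drug, c("meropenem", "piperacillin"))
  stopifnot(length(start) == length(duration),
            length(start) == length(amount),
            all(duration > 0), all(amount > 0), all(start >= 0), tau > 0)
  o <- order(start)
  events <- data.frame(start = start[o], duration = duration[o],
                       amount = amount[o])
  events$rate <- events$amount / events$duration
  structure(list(drug = drug, loading_amount = events$amount[1L],
                 maintenance_amount = events$amount[min(2L, nrow(events))],
                 tau = tau, loading_duration = events$duration[1L],
                 maintenance_duration = events$duration[min(2L, nrow(events))],
                 horizon = horizon, events = events),
            class = "fd_regimen")
}

#' @export
print.fd_regimen <- function(x, ...) {
  cat(sprintf("<%s regimen> %g mg/%g h loading + %g mg/%g h q%gh (%d infusions over %g h)\n",
              x$drug, x$loading_amount, x$loading_duration,
              x$maintenance_amount, x$maintenance_duration, x$tau,
              nrow(x$events), x$horizon))
  invisible(x)
}
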