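# Independent numerical ODE oracle for the two-compartment infusion model:
# integrates dA1/dt = R(t) - (k10 + k12) A1 + k21 A2, dA2/dt = k12 A1 - k21 A2
# piecewise between infusion knots (so the rate is constant on every
# integrated segment) and returns C = A1 / V1 at the requested times.
ode_oracle <- function(p, regimen, t_eval) {
  ev <- regimen$events
  knots <- sort(unique(c(0, ev$start, ev$start + ev$duration, t_eval)))
  knots <- knots[knots <= max(t_eval)]
  deriv <- function(t, y, parms) {
    list(c(parms$rate - (p$k10 + p$k12) * y[1] + p$k21 * y[2],
           p$k12 * y[1] - p$k21 * y[2]))
  }
  state <- c(A1 = 0, A2 = 0)
  out_c <- stats::setNames(numeric(length(t_eval)), as.character(t_eval))
  if (any(t_eval == 0)) out_c[as.character(0)] <- 0
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    mid <- (a + b) / 2
    rate <- sum(ev$rate[ev$start <= mid & mid < ev$start + ev$duration])
    sol <- deSolve::lsoda(state, c(a, b), deriv, parms = list(rate = rate),
                          rtol = 1e-12, atol = 1e-12)
    state <- sol[nrow(sol), c("A1", "A2")]
    hit <- t_eval == b
    if (any(hit)) out_c[hit] <- state[["A1"]] / p$V1
  }
  unname(out_c)
}

# random structural parameters and regimens spanning realistic ICU ranges
random_params <- function() {
  structural_params(CL = runif(1, 3, 30), V1 = runif(1, 5, 30),
                    Q = runif(1, 2, 20), V2 = runif(1, 5, 30))
}

random_regimen <- function() {
  drug <- sample(c("meropenem", "piperacillin"), 1)
  tau <- sample(c(6, 8, 12), 1)
  dosing_regimen(drug,
                 loading_amount = sample(c(500, 1000, 2000, 4000), 1),
                 maintenance_amount = sample(c(1000, 2000, 4000), 1),
                 tau = tau, horizon = 24)
}

# brute-force time-above-threshold on a regular grid (midpoint rule)
grid_time_above <- function(p, regimen, thr, t1, dt = 1e-3) {
  tt <- seq(0, t1, by = dt)
  mids <- (tt[-1] + tt[-length(tt)]) / 2
  cc <- concentration_at(p, regimen, mids)
  sum(cc > thr) * dt
}

# independent full-enumeration oracle for the two-sided exact rank-sum p
enum_wilcox_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  ws <- apply(idx, 2, function(i) sum(rank(pooled)[i]) - m * (m + 1) / 2)
  # two-sided: double the smaller tail
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# a compact noise-free toy: one-compartment, omega on CL and V1 only
toy_pop <- function(a = 0.5, b = 0.1, omega = c(CL = 0.3, V1 = 0.3)) {
  pop_model("meropenem", structural_params(CL = 10, V1 = 20),
            covariate_effects = NULL, omega = omega,
            error_additive = a, error_proportional = b)
}
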