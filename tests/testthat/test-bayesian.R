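test_that("log posterior equals the hand-computed Gaussian densities", {
  # 1 parameter (CL), 1 observation, one-compartment model
  pop <- toy_pop(a = 0.5, b = 0.1, omega = c(CL = 0.3))
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  obs <- observation_set(2, 30, role = "end_infusion")
  eta <- 0.12
  p <- structural_params(10 * exp(eta), 20)
  f <- concentration_at(p, r, 2)
  g <- 0.5 + 0.1 * f
  by_hand <- -0.5 * log(2 * pi * 0.3^2) - eta^2 / (2 * 0.3^2) +
    -0.5 * log(2 * pi * g^2) - (30 - f)^2 / (2 * g^2)
  expect_equal(log_posterior(eta, obs, pop, regimen = r), by_hand,
               tolerance = 1e-12)
  # prior is maximal at eta = 0 with no observations
  none <- observation_set(numeric(0), numeric(0), character(0), logical(0))
  expect_gt(log_posterior(0, none, pop, regimen = r),
            log_posterior(0.2, none, pop, regimen = r))
  # an observation at its prediction rewards the matching eta
  obs_match <- observation_set(2, concentration_at(p, r, 2),
                               role = "end_infusion")
  pop_tight <- toy_pop(a = 0.05, b = 0, omega = c(CL = 0.3))
  expect_gt(log_posterior(eta, obs_match, pop_tight, regimen = r),
            log_posterior(eta + 0.5, obs_match, pop_tight, regimen = r))
  expect_error(log_posterior(c(0, 0), obs, pop, regimen = r), "dimension")
})

test_that("zero observations give the prior mode: eta exactly 0", {
  pop <- default_model("meropenem")
  cov <- patient_covariates("P1", 58, "male", 83, 178, 58, 8, FALSE)
  crcl <- crcl_cockcroft_gault(cov)
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  none <- observation_set(numeric(0), numeric(0), character(0), logical(0))
  fit <- map_fit(none, pop, cov, crcl, r)
  expect_true(fit$converged)
  expect_identical(unname(fit$eta_mode), rep(0, 4))
  expect_identical(fit$n_obs_used, 0L)
  # individual parameters are the covariate-adjusted typical values
  expect_equal(fit$individual$CL,
               individual_parameters(pop, cov, crcl,
                                     rep(0, 4))$CL)
})

test_that("noise-free rich sampling recovers the generating random effects", {
  pop <- pop_model("meropenem", structural_params(12, 12, 8, 8),
                   omega = c(CL = 0.35, V1 = 0.3, Q = 0.25, V2 = 0.25),
                   error_additive = 1e-4, error_proportional = 0)
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  eta_star <- c(CL = 0.2, V1 = -0.1, Q = 0, V2 = 0)
  p_star <- individual_parameters(pop, eta = eta_star)
  tt <- c(0.25, 0.5, 1, 2, 3.5, 5, 6.5, 8.5)
  obs <- observation_set(tt, concentration_at(p_star, r, tt),
                         role = rep("trough", 8))
  fit <- map_fit(obs, pop, regimen = r)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$eta_mode - eta_star)), 0.01)
})

test_that("MAP solution matches a brute-force grid search in a 2-parameter toy", {
  pop <- toy_pop(a = 1, b = 0.1, omega = c(CL = 0.3, V1 = 0.3))
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  tt <- c(0.5, 3.4, 8.5)
  yy <- c(38, 26, 7)
  obs <- observation_set(tt, yy, role = c("post_loading_cmax",
                                          "end_infusion", "trough"))
  # independent oracle: vectorised one-compartment likelihood on a grid
  gr <- seq(-1, 1, by = 0.005)
  grid <- expand.grid(eCL = gr, eV1 = gr)
  CL <- 10 * exp(grid$eCL); V1 <- 20 * exp(grid$eV1)
  lp <- -(grid$eCL^2 + grid$eV1^2) / (2 * 0.3^2)
  for (j in seq_along(tt)) {
    f <- 0
    for (i in seq_len(nrow(r$events))) {
      ev <- r$events[i, ]
      tau <- tt[j] - ev$start
      if (tau <= 0) next
      k <- CL / V1
      css <- ev$rate / CL
      f <- f + ifelse(rep(tau, nrow(grid)) <= ev$duration,
                      css * (1 - exp(-k * tau)),
                      css * (1 - exp(-k * ev$duration)) *
                        exp(-k * (tau - ev$duration)))
    }
    g <- 1 + 0.1 * f
    lp <- lp - log(g) - (yy[j] - f)^2 / (2 * g^2)
  }
  best <- grid[which.max(lp), ]
  fit <- map_fit(obs, pop, regimen = r)
  expect_true(fit$converged)
  expect_lt(abs(fit$eta_mode[["CL"]] - best$eCL), 0.02)
  expect_lt(abs(fit$eta_mode[["V1"]] - best$eV1), 0.02)
})

test_that("growing residual error shrinks the conditional mode toward zero", {
  pop0 <- default_model("piperacillin")
  r <- dosing_regimen("piperacillin", 4000, 4000, tau = 6)
  p_true <- individual_parameters(pop0, eta = c(CL = 0.5, V1 = 0.3,
                                                Q = 0, V2 = 0))
  tt <- c(0.5, 3.4, 6.5)
  obs <- observation_set(tt, concentration_at(p_true, r, tt),
                         role = c("post_loading_cmax", "end_infusion",
                                  "trough"))
  # scale the additive error component: with observation noise growing the
  # prior dominates and the conditional mode contracts toward zero
  norms <- vapply(c(0.5, 4, 32), function(a) {
    pop <- pop_model("piperacillin", pop0$typical, omega = pop0$omega,
                     error_additive = a, error_proportional = 0)
    sqrt(sum(map_fit(obs, pop, regimen = r)$eta_mode^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("BLQ observations are excluded with a warning", {
  pop <- toy_pop()
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  obs <- observation_set(c(0.5, 8.5), c(30, 0.05),
                         role = c("post_loading_cmax", "trough"),
                         blq = c(FALSE, TRUE))
  expect_warning(fit <- map_fit(obs, pop, regimen = r), "BLQ")
  expect_identical(fit$n_obs_used, 1L)
})

test_that("MH conditional mode agrees with the deterministic MAP", {
  pop <- default_model("meropenem")
  cov <- patient_covariates("P1", 50, "male", 80, 180, 70, 6, FALSE)
  crcl <- crcl_cockcroft_gault(cov)
  r <- dosing_regimen("meropenem", 1000, 1000, tau = 8)
  none <- observation_set(numeric(0), numeric(0), character(0), logical(0))
  mh0 <- conditional_mode_mh(none, pop, cov, crcl, r, seed = 5)
  expect_lt(max(abs(mh0$eta_mode)), 0.05)

  set.seed(31)
  for (i in 1:5) {
    eta <- rnorm(4, 0, pop$omega)
    p <- individual_parameters(pop, cov, crcl, setNames(eta,
                                                        names(pop$omega)))
    obs <- simulate_observations(p, r, pop, jitter_sd = 0.2)
    map <- map_fit(obs, pop, cov, crcl, r)
    mh <- conditional_mode_mh(obs, pop, cov, crcl, r, seed = 100 + i)
    expect_lt(abs(mh$objective - map$objective), 0.1)
  }
  # bit-identical under a fixed seed
  obs1 <- observation_set(c(0.5, 3.4, 8.4), c(50, 30, 3),
                          role = c("post_loading_cmax", "end_infusion",
                                   "trough"))
  a <- conditional_mode_mh(obs1, pop, cov, crcl, r, seed = 77)
  b <- conditional_mode_mh(obs1, pop, cov, crcl, r, seed = 77)
  expect_identical(a, b)
  expect_error(conditional_mode_mh(obs1, pop, cov, crcl, r, seed = 1,
                                   scale = 0), "proposal")
})
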