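#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a general-ICU first-dose beta-lactam cohort: covariate
#' location/spread anchors (median and IQR), regimen mixes, the three-sample
#' sparse schedule with timing jitter, and log-normal between-subject
#' variability with combined residual noise. Ages and heights are sampled
#' from truncated normals, weight and creatinine from log-normals whose
#' median/IQR match the anchors.
#'
#' @param n_meropenem,n_piperacillin Cohort sizes.
#' @param seed Integer seed (mandatory).
#' @param trough_jitter_sd SD (hours) of the truncated-normal trough-time
#'   deviation; default 0.25 h puts ~95% of troughs within +/- 0.5 h of the
#'   nominal interval end. Jitter is truncated at +/- 1 h.
#' @param arc_fraction Optional target fraction of patients with CrCL > 130
#'   mL/min (achieved by covariate resampling); `NULL` leaves the natural
#'   fraction implied by the covariate distributions.
#' @param arc_eta_correlation For the covariate-free piperacillin model:
#'   correlation between the clearance random effect and the patient's
#'   (log) creatinine clearance, emulating renally driven clearance.
#' @param covariates,regimen_mix Override lists; see the package source for
#'   the default structure.
#' @return An `fd_cohort_config`.
#' @export
cohort_config <- function(n_meropenem = 22, n_piperacillin = 48, seed,
                          trough_jitter_sd = 0.25, arc_fraction = NULL,
                          arc_eta_correlation = c(meropenem = 0,
                                                  piperacillin = 0.6),
                          covariates = NULL, regimen_mix = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_meropenem >= 0, n_piperacillin >= 0, trough_jitter_sd >= 0)
  default_cov <- list(
    meropenem = list(
      age = list(dist = "normal", median = 58, iqr = c(46, 69),
                 lower = 18, upper = 100),
      height = list(dist = "normal", median = 178, iqr = c(175, 180),
                    lower = 140, upper = 210),
      weight = list(dist = "lognormal", median = 83, iqr = c(68, 94)),
      creatinine = list(dist = "lognormal", median = 58, iqr = c(46, 78)),
      sofa = list(median = 8, iqr = c(6, 10)),
      male_fraction = 0.73, trauma_fraction = 0.41),
    piperacillin = list(
      age = list(dist = "normal", median = 63, iqr = c(46, 70),
                 lower = 18, upper = 100),
      height = list(dist = "normal", median = 175, iqr = c(168, 182),
                    lower = 140, upper = 210),
      weight = list(dist = "lognormal", median = 85, iqr = c(72, 101)),
      creatinine = list(dist = "lognormal", median = 74, iqr = c(59, 94)),
      sofa = list(median = 8, iqr = c(7, 10)),
      male_fraction = 0.73, trauma_fraction = 0.17))
  default_mix <- list(
    meropenem = data.frame(
      loading = c(1000, 2000, 1000, 500),
      maintenance = c(1000, 2000, 2000, 1000),
      tau = c(8, 8, 8, 8),
      prob = c(0.50, 0.27, 0.14, 0.09)),
    piperacillin = data.frame(
      loading = c(4000, 4000, 2000),
      maintenance = c(4000, 4000, 2000),
      tau = c(6, 8, 12),
      prob = c(0.71, 0.19, 0.10)))
  cov <- covariates %||% default_cov
  mix <- regimen_mix %||% default_mix
  for (d in names(mix))
    if (abs(sum(mix[[d]]$prob) - 1) > 1e-8)
      stop("regimen mix probabilities for ", d, " must sum to 1",
           call. = FALSE)
  structure(list(n_meropenem = n_meropenem, n_piperacillin = n_piperacillin,
                 seed = as.integer(seed),
                 trough_jitter_sd = trough_jitter_sd,
                 arc_fraction = arc_fraction,
                 arc_eta_correlation = arc_eta_correlation,
                 covariates = cov, regimen_mix = mix),
            class = "fd_cohort_config")
}

# IQR -> scale: for a normal, sd = IQR width / (2 * qnorm(.75)); for a
# log-normal the same on the log scale
.iqr_sd <- function(iqr) (iqr[2L] - iqr[1L]) / (2 * stats::qnorm(0.75))

.draw_anchor <- function(a, n) {
  if (a$dist == "lognormal") {
    stats::rlnorm(n, log(a$median), .iqr_sd(log(a$iqr)))
  } else {
    v <- stats::rnorm(n, a$median, .iqr_sd(a$iqr))
    # truncate by resampling
    bad <- v < a$lower | v > a$upper
    while (any(bad)) {
      v[bad] <- stats::rnorm(sum(bad), a$median, .iqr_sd(a$iqr))
      bad <- v < a$lower | v > a$upper
    }
    v
  }
}

#' Sample one patient's covariates
#'
#' Uses the current RNG state; seed the session (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param config An `fd_cohort_config`.
#' @param drug Drug arm.
#' @param patient_id Identifier.
#' @return An `fd_covariates`.
#' @export
sample_covariates <- function(config, drug, patient_id = "S1") {
  a <- config$covariates[[drug]]
  # with a target ARC fraction, decide the patient's ARC status first and
  # resample covariates until it is met
  want_arc <- if (is.null(config$arc_fraction)) NA
  else stats::runif(1) < config$arc_fraction
  repeat {
    cov <- patient_covariates(
      patient_id = patient_id,
      age = .draw_anchor(a$age, 1L),
      sex = if (stats::runif(1) < a$male_fraction) "male" else "female",
      weight = .draw_anchor(a$weight, 1L),
      height = .draw_anchor(a$height, 1L),
      serum_creatinine = .draw_anchor(a$creatinine, 1L),
      sofa = max(0L, as.integer(round(stats::rnorm(1, a$sofa$median,
                                                   .iqr_sd(a$sofa$iqr))))),
      trauma_admission = stats::runif(1) < a$trauma_fraction)
    if (is.na(want_arc) ||
        (crcl_cockcroft_gault(cov) > 130) == want_arc) return(cov)
  }
}

#' Draw a dosing regimen from the configured mix
#'
#' @param config An `fd_cohort_config`.
#' @param drug Drug arm.
#' @return An `fd_regimen`.
#' @export
assign_regimen <- function(config, drug) {
  mix <- config$regimen_mix[[drug]]
  i <- sample.int(nrow(mix), 1L, prob = mix$prob)
  dosing_regimen(drug, mix$loading[i], mix$maintenance[i], mix$tau[i],
                 horizon = max(24, mix$tau[i] + 1))
}

# standardised log-CrCL against the per-drug reference distribution implied
# by the covariate anchors; used to correlate eta_CL with renal function for
# the covariate-free model
.renal_z <- function(config, drug, crcl) {
  ref <- if (drug == "meropenem") c(144, 99, 176) else c(112, 70, 147)
  (log(crcl) - log(ref[1L])) / .iqr_sd(log(ref[2:3]))
}

#' Simulate the three-sample sparse observation schedule
#'
#' Samples at the end of the loading dose (t = 0.5 h), during the last 15
#' minutes of the first extended infusion (uniform on [3.25, 3.5] h for the
#' default 3 h infusion), and a trough at the interval end plus a
#' truncated-normal timing jitter (+/- 1 h truncation). Noise follows the
#' model's combined residual error: `y = f * (1 + b e2) + a e1`; draws are
#' repeated until positive, and values below 0.1 mg/L are flagged BLQ.
#'
#' @param p True individual `fd_params`.
#' @param regimen An `fd_regimen`.
#' @param pop An `fd_pop_model` (for the error coefficients).
#' @param jitter_sd Trough timing jitter SD in hours.
#' @param noise Logical; `FALSE` returns noise-free observations at the
#'   same (still jittered) times.
#' @return An `fd_obs` with attribute `noise_free` (the exact
#'   concentrations at the sampled times).
#' @export
simulate_observations <- function(p, regimen, pop, jitter_sd = 0.25,
                                  noise = TRUE) {
  t1 <- regimen$loading_duration
  inf_end <- regimen$loading_duration + regimen$maintenance_duration
  t2 <- stats::runif(1, inf_end - 0.25, inf_end)
  jitter <- if (jitter_sd > 0) {
    j <- stats::rnorm(1, 0, jitter_sd)
    while (abs(j) > 1) j <- stats::rnorm(1, 0, jitter_sd)
    j
  } else 0
  t3 <- max(interval_end(regimen) + jitter, inf_end + 0.1)
  times <- c(t1, t2, t3)
  f <- concentration_at(p, regimen, times)
  if (noise) {
    y <- vapply(f, function(fi) {
      repeat {
        yi <- fi * (1 + pop$error_proportional * stats::rnorm(1)) +
          pop$error_additive * stats::rnorm(1)
        if (yi > 0) return(yi)
      }
    }, numeric(1))
  } else y <- f
  out <- observation_set(times, y,
                         role = c("post_loading_cmax", "end_infusion",
                                  "trough"),
                         blq = y < 0.1)
  attr(out, "noise_free") <- f
  out
}

#' Generate a synthetic cohort
#'
#' Draws covariates, regimens, true random effects (with the configured
#' renal linkage of clearance for the covariate-free piperacillin model),
#' true individual parameters, renal assessments, and noisy three-sample
#' observation sets for every patient.
#'
#' @param config An `fd_cohort_config`.
#' @param models Named list of `fd_pop_model`s; defaults to the bundled
#'   models.
#' @return An `fd_cohort`: list with data frames `patients`, `doses`,
#'   `observations`, `truth`, `renal`, and a per-patient `records` list
#'   (each with `cov`, `regimen`, `renal`, `eta`, `params`, `obs`).
#' @export
generate_cohort <- function(config,
                            models = list(
                              meropenem = default_model("meropenem"),
                              piperacillin = default_model("piperacillin"))) {
  stopifnot(inherits(config, "fd_cohort_config"))
  set.seed(config$seed)
  plan <- data.frame(
    drug = rep(c("meropenem", "piperacillin"),
               c(config$n_meropenem, config$n_piperacillin)))
  plan$patient_id <- sprintf("S%03d", seq_len(nrow(plan)))
  records <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    drug <- plan$drug[i]
    pop <- models[[drug]]
    cov <- sample_covariates(config, drug, plan$patient_id[i])
    regimen <- assign_regimen(config, drug)
    ren <- renal_assessment(cov)
    eta <- stats::rnorm(length(pop$omega), 0, pop$omega)
    names(eta) <- names(pop$omega)
    rho <- config$arc_eta_correlation[[drug]]
    if (!is.null(rho) && rho != 0 && "CL" %in% names(eta)) {
      z <- .renal_z(config, drug, ren$crcl)
      eta[["CL"]] <- pop$omega[["CL"]] *
        (rho * z + sqrt(1 - rho^2) * eta[["CL"]] / pop$omega[["CL"]])
    }
    params <- individual_parameters(pop, cov, ren$crcl, eta)
    obs <- simulate_observations(params, regimen, pop,
                                 jitter_sd = config$trough_jitter_sd)
    records[[i]] <- list(cov = cov, regimen = regimen, renal = ren,
                         eta = eta, params = params, obs = obs)
  }
  structure(c(.cohort_frames(plan, records), list(records = records,
                                                  seed = config$seed)),
            class = "fd_cohort")
}

# flatten per-patient records into the CSV-facing data frames
.cohort_frames <- function(plan, records) {
  patients <- do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(patient_id = r$cov$patient_id, drug = plan$drug[i],
               age_y = r$cov$age, sex = r$cov$sex,
               weight_kg = r$cov$weight, height_cm = r$cov$height,
               creatinine_umol_L = r$cov$serum_creatinine,
               sofa = r$cov$sofa,
               trauma = as.integer(r$cov$trauma_admission),
               loading_mg = r$regimen$loading_amount,
               maintenance_mg = r$regimen$maintenance_amount,
               tau_h = r$regimen$tau)
  }))
  doses <- do.call(rbind, lapply(records, function(r) {
    ev <- r$regimen$events
    data.frame(patient_id = r$cov$patient_id, start_h = ev$start,
               duration_h = ev$duration, amount_mg = ev$amount)
  }))
  observations <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$cov$patient_id, time_h = r$obs$time,
               conc_mg_L = r$obs$conc, role = r$obs$role,
               blq = as.integer(r$obs$blq))
  }))
  truth <- do.call(rbind, lapply(records, function(r) {
    eta <- stats::setNames(as.list(r$eta), paste0("eta_", names(r$eta)))
    cbind(data.frame(patient_id = r$cov$patient_id),
          as.data.frame(eta),
          data.frame(CL = r$params$CL, V1 = r$params$V1,
                     Q = r$params$Q, V2 = r$params$V2))
  }))
  renal <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$renal$patient_id,
               relative_egfr = r$renal$relative_egfr, bsa = r$renal$bsa,
               absolute_egfr = r$renal$absolute_egfr, crcl = r$renal$crcl,
               arc_score = r$renal$arc_score, arc = r$renal$arc,
               suspected_arc = r$renal$suspected_arc,
               egfr_group = r$renal$egfr_group)
  }))
  list(patients = patients, doses = doses, observations = observations,
       truth = truth, renal = renal)
}

#' @export
print.fd_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort> %d patients (%d meropenem, %d piperacillin), seed %d\n",
              nrow(x$patients), sum(x$patients$drug == "meropenem"),
              sum(x$patients$drug == "piperacillin"), x$seed))
  invisible(x)
}
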