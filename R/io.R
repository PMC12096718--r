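#' Write a synthetic cohort to CSV files
#'
#' Emits `patients.csv`, `doses.csv`, `observations.csv`, `truth.csv` and
#' `renal.csv` under `dir`. Every file carries a comment header with the
#' generator seed. Times are decimal hours from the start of the loading
#' dose; concentrations mg/L; creatinine umol/L.
#'
#' @param cohort An `fd_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("patients", "doses", "observations", "truth", "renal")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# firstdose cohort; seed %d", cohort$seed), con)
    utils::write.csv(cohort[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

.read_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read patient data from the documented CSV schemas
#'
#' `patients_csv` columns: patient_id, drug, age_y, sex, weight_kg,
#' height_cm, creatinine_umol_L, sofa, trauma (0/1), loading_mg,
#' maintenance_mg, tau_h. `observations_csv` columns: patient_id, time_h,
#' conc_mg_L, role, blq (0/1). Row-level validation failures are reported
#' with their row numbers.
#'
#' @param patients_csv,observations_csv File paths.
#' @return A list of per-patient records (`cov`, `regimen`, `obs`).
#' @export
read_patient_data <- function(patients_csv, observations_csv) {
  pts <- .read_csv(patients_csv)
  obs <- .read_csv(observations_csv)
  need <- c("patient_id", "drug", "age_y", "sex", "weight_kg", "height_cm",
            "creatinine_umol_L", "sofa", "trauma", "loading_mg",
            "maintenance_mg", "tau_h")
  missing_cols <- setdiff(need, names(pts))
  if (length(missing_cols))
    stop("patients file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!pts$drug %in% c("meropenem", "piperacillin"))
  if (length(bad))
    stop("unknown drug label in patients rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(pts$age_y <= 0 | pts$weight_kg <= 0 | pts$height_cm <= 0 |
                 pts$creatinine_umol_L <= 0)
  if (length(bad))
    stop("non-positive covariate in patients rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(obs$blq == 0 & obs$conc_mg_L <= 0)
  if (length(bad))
    stop("non-positive concentration in observation rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(pts)), function(i) {
    r <- pts[i, ]
    oi <- obs[obs$patient_id == r$patient_id, , drop = FALSE]
    oi <- oi[order(oi$time_h), , drop = FALSE]
    list(cov = patient_covariates(r$patient_id, r$age_y, r$sex, r$weight_kg,
                                  r$height_cm, r$creatinine_umol_L, r$sofa,
                                  r$trauma == 1),
         regimen = dosing_regimen(r$drug, r$loading_mg, r$maintenance_mg,
                                  r$tau_h, horizon = max(24, r$tau_h + 1)),
         obs = observation_set(oi$time_h, oi$conc_mg_L, oi$role,
                               oi$blq == 1))
  })
}

#' Read a NONMEM-style event table
#'
#' Accepts the classic columns ID, TIME, AMT, RATE, DV, EVID, MDV (CSV,
#' comment lines starting with `#` ignored). Dose records (EVID 1) become
#' infusion events with duration AMT/RATE; observation records (EVID 0,
#' MDV 0) become the observation set. Roles are inferred from timing
#' relative to the reconstructed regimen.
#'
#' @param path File path.
#' @param drug Drug label to attach (the table does not carry it).
#' @param tau Dosing interval in hours; if `NULL`, inferred from the gap
#'   between the second and third dose starts (falling back to 8).
#' @return A list of per-patient records (`regimen`, `obs`).
#' @export
read_event_table <- function(path, drug, tau = NULL) {
  ev <- .read_csv(path)
  names(ev) <- toupper(names(ev))
  need <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")
  if (!all(need %in% names(ev)))
    stop("event table lacks columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "), call. = FALSE)
  lapply(split(ev, ev$ID), function(e) {
    dose <- e[e$EVID == 1, , drop = FALSE]
    o <- e[e$EVID == 0 & e$MDV == 0, , drop = FALSE]
    if (nrow(dose) == 0) stop("subject without dose records", call. = FALSE)
    dur <- dose$AMT / dose$RATE
    tau_i <- tau
    if (is.null(tau_i))
      tau_i <- if (nrow(dose) >= 3) dose$TIME[3L] - dose$TIME[2L] else 8
    reg <- regimen_from_events(drug, dose$TIME, dur, dose$AMT, tau_i,
                               horizon = max(24, max(dose$TIME) + tau_i))
    inf_end <- reg$loading_duration + reg$maintenance_duration
    role <- ifelse(o$TIME <= reg$loading_duration + 0.25,
                   "post_loading_cmax",
                   ifelse(o$TIME <= inf_end + 0.25, "end_infusion",
                          "trough"))
    list(regimen = reg,
         obs = observation_set(o$TIME, o$DV, role, rep(FALSE, nrow(o))))
  })
}

#' Run the full first-dose analysis pipeline
#'
#' generate (or load) -> renal assessment -> MAP fits -> exposure metrics ->
#' cohort statistics. With `out_dir` set, writes `exposure.csv`,
#' `cohort_summary.csv`, `comparisons.csv`, `roc.csv`, `fits.csv` and
#' `run_log.txt`, each headed by the seed and configuration hash; identical
#' configuration and seed reproduce identical files.
#'
#' @param cohort An `fd_cohort` from [generate_cohort()], or a record list
#'   from [read_patient_data()] (in which case renal assessments are
#'   computed here).
#' @param models Named list of population models.
#' @param targets Named list of `fd_target`s per drug.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in output headers (defaults to the cohort's).
#' @return An `fd_report`: data frames `fits`, `exposure`, summary list
#'   `summary`, `comparisons` (list of `fd_comparison`), `roc` (per drug),
#'   and counts of non-converged fits.
#' @export
run_pipeline <- function(cohort,
                         models = list(
                           meropenem = default_model("meropenem"),
                           piperacillin = default_model("piperacillin")),
                         targets = list(
                           meropenem = default_target("meropenem"),
                           piperacillin = default_target("piperacillin")),
                         out_dir = NULL, seed = NULL) {
  if (inherits(cohort, "fd_cohort")) {
    records <- cohort$records
    renal_df <- cohort$renal
    patients_df <- cohort$patients
    seed <- seed %||% cohort$seed
  } else {
    records <- cohort
    renal <- lapply(records, function(r) renal_assessment(r$cov))
    renal_df <- do.call(rbind, lapply(renal, function(x)
      data.frame(patient_id = x$patient_id, relative_egfr = x$relative_egfr,
                 bsa = x$bsa, absolute_egfr = x$absolute_egfr, crcl = x$crcl,
                 arc_score = x$arc_score, arc = x$arc,
                 suspected_arc = x$suspected_arc,
                 egfr_group = x$egfr_group)))
    for (i in seq_along(records)) records[[i]]$renal <- renal[[i]]
    patients_df <- do.call(rbind, lapply(records, function(r)
      data.frame(patient_id = r$cov$patient_id, drug = r$regimen$drug,
                 age_y = r$cov$age, sex = r$cov$sex,
                 weight_kg = r$cov$weight, height_cm = r$cov$height,
                 creatinine_umol_L = r$cov$serum_creatinine,
                 sofa = r$cov$sofa,
                 trauma = as.integer(r$cov$trauma_admission),
                 loading_mg = r$regimen$loading_amount,
                 maintenance_mg = r$regimen$maintenance_amount,
                 tau_h = r$regimen$tau)))
    seed <- seed %||% NA_integer_
  }

  fit_rows <- list(); expo_rows <- list(); n_failed <- 0L
  for (r in records) {
    drug <- r$regimen$drug
    pop <- models[[drug]]
    fit <- suppressWarnings(
      map_fit(r$obs, pop, r$cov, r$renal$crcl, r$regimen))
    fr <- data.frame(patient_id = r$cov$patient_id, drug = drug,
                     converged = fit$converged,
                     objective = fit$objective,
                     n_obs_used = fit$n_obs_used)
    if (fit$converged) {
      fr$CL <- fit$individual$CL; fr$V1 <- fit$individual$V1
      fr$Q <- fit$individual$Q; fr$V2 <- fit$individual$V2
      for (nm in names(fit$eta_mode))
        fr[[paste0("eta_", nm)]] <- fit$eta_mode[[nm]]
      ex <- exposure_summary(fit, r$obs, r$regimen, targets[[drug]])
      expo_rows[[length(expo_rows) + 1L]] <- cbind(
        data.frame(patient_id = r$cov$patient_id, drug = drug),
        as.data.frame(unclass(ex)))
    } else {
      n_failed <- n_failed + 1L
      fr$CL <- NA_real_; fr$V1 <- NA_real_; fr$Q <- NA_real_
      fr$V2 <- NA_real_
    }
    fit_rows[[length(fit_rows) + 1L]] <- fr
  }
  fits <- do.call(rbind, lapply(fit_rows, function(x) {
    miss <- setdiff(unique(unlist(lapply(fit_rows, names))), names(x))
    for (m in miss) x[[m]] <- NA_real_
    x
  }))
  exposure <- do.call(rbind, expo_rows)

  bundle <- list(patients = patients_df, renal = renal_df,
                 exposure = exposure)
  summary <- summarize_cohort(bundle)

  comparisons <- list(); roc <- list()
  for (d in unique(exposure$drug)) {
    e <- exposure[exposure$drug == d, , drop = FALSE]
    ri <- renal_df[match(e$patient_id, renal_df$patient_id), , drop = FALSE]
    hi <- ri$egfr_group == "above_90"
    ok_cmin <- !is.na(e$cmin_observed)
    if (sum(hi & ok_cmin) && sum(!hi & ok_cmin)) {
      comparisons[[paste0(d, "_cmin_by_egfr")]] <-
        wilcoxon_exact(e$cmin_observed[hi & ok_cmin],
                       e$cmin_observed[!hi & ok_cmin],
                       labels = c("eGFR>90", "eGFR<=90"))
      comparisons[[paste0(d, "_halflife_by_egfr")]] <-
        wilcoxon_exact(e$terminal_half_life[hi], e$terminal_half_life[!hi],
                       labels = c("eGFR>90", "eGFR<=90"))
    }
    ok <- !is.na(e$cmin_cmax_ratio)
    arc <- ri$suspected_arc
    if (sum(ok & arc) && sum(ok & !arc)) {
      comparisons[[paste0(d, "_ratio_by_arc")]] <-
        wilcoxon_exact(e$cmin_cmax_ratio[ok & arc],
                       e$cmin_cmax_ratio[ok & !arc],
                       labels = c("suspected ARC", "no ARC"))
      if (length(unique(e$cmin_cmax_ratio[ok])) >= 2L)
        roc[[d]] <- roc_cutoff(e$cmin_cmax_ratio[ok], arc[ok])
    }
  }

  report <- structure(list(fits = fits, exposure = exposure,
                           summary = summary, comparisons = comparisons,
                           roc = roc, n_not_converged = n_failed,
                           seed = seed),
                      class = "fd_report")
  if (!is.null(out_dir)) .write_report(report, bundle, out_dir, models)
  report
}

.config_hash <- function(models) {
  txt <- paste(utils::capture.output(utils::str(models)), collapse = "\n")
  # stable short hash without extra dependencies
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 1e9
}

.write_report <- function(report, bundle, out_dir, models) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# firstdose report; seed %s; config hash %d",
                 as.character(report$seed), .config_hash(models))
  wr <- function(df, name) {
    con <- file(file.path(out_dir, name), "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(report$fits, "fits.csv")
  wr(report$exposure, "exposure.csv")
  wr(report$summary$attainment, "cohort_summary.csv")
  comp <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
    cc <- report$comparisons[[nm]]
    data.frame(comparison = nm, n1 = cc$n[1L], n2 = cc$n[2L],
               median1 = cc$median[1L], median2 = cc$median[2L],
               p_value = cc$p_value, shift = cc$shift_estimate,
               conf_low = cc$conf_low, conf_high = cc$conf_high)
  }))
  if (!is.null(comp)) wr(comp, "comparisons.csv")
  rocdf <- do.call(rbind, lapply(names(report$roc), function(d)
    data.frame(drug = d, cutoff = report$roc[[d]]$cutoff,
               sensitivity = report$roc[[d]]$sensitivity,
               specificity = report$roc[[d]]$specificity,
               youden_j = report$roc[[d]]$youden_j)))
  if (!is.null(rocdf)) wr(rocdf, "roc.csv")
  log <- c(hdr,
           sprintf("R version: %s", getRversion()),
           sprintf("patients: %d; fits not converged: %d",
                   nrow(report$fits), report$n_not_converged))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}

#' @export
print.fd_report <- function(x, ...) {
  cat(sprintf("<firstdose report> %d patients, %d fit(s) not converged\n",
              nrow(x$fits), x$n_not_converged))
  print(x$summary$attainment)
  invisible(x)
}
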