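#' Exact Wilcoxon rank-sum comparison with Hodges-Lehmann shift interval
#'
#' Two-sided exact test (full conditional distribution; normal approximation
#' with tie correction for combined n > 25 or in the presence of ties), with
#' the Hodges-Lehmann location-shift estimate and its exact-inversion 95%
#' confidence interval.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param labels Length-2 character vector naming the groups.
#' @param conf_level Confidence level, default 0.95.
#' @return An `fd_comparison`: group sizes, medians and IQRs, `p_value`,
#'   `shift_estimate`, `conf_low`, `conf_high`.
#' @export
wilcoxon_exact <- function(x, y, labels = c("x", "y"), conf_level = 0.95) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups: degenerate comparison",
            call. = FALSE)
    return(structure(list(labels = labels, n = c(length(x), length(y)),
                          median = c(stats::median(x), stats::median(y)),
                          iqr = rbind(stats::quantile(x, c(.25, .75)),
                                      stats::quantile(y, c(.25, .75))),
                          p_value = 1, shift_estimate = 0,
                          conf_low = NA_real_, conf_high = NA_real_,
                          exact = FALSE),
                     class = "fd_comparison"))
  }
  exact <- !ties && (length(x) + length(y)) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact,
                       conf.int = TRUE, conf.level = conf_level))
  structure(list(labels = labels, n = c(length(x), length(y)),
                 median = c(stats::median(x), stats::median(y)),
                 iqr = rbind(stats::quantile(x, c(.25, .75)),
                             stats::quantile(y, c(.25, .75))),
                 p_value = unname(wt$p.value),
                 shift_estimate = unname(wt$estimate),
                 conf_low = unname(wt$conf.int[1L]),
                 conf_high = unname(wt$conf.int[2L]),
                 exact = exact),
            class = "fd_comparison")
}

#' @export
print.fd_comparison <- function(x, ...) {
  cat(sprintf("<comparison %s (n=%d) vs %s (n=%d)> p = %.4g (%s)\n",
              x$labels[1L], x$n[1L], x$labels[2L], x$n[2L], x$p_value,
              if (x$exact) "exact" else "normal approx."))
  cat(sprintf("  medians %.3g vs %.3g; shift %.3g [%.3g, %.3g]\n",
              x$median[1L], x$median[2L], x$shift_estimate,
              x$conf_low, x$conf_high))
  invisible(x)
}

#' ROC-optimal cutoff for a "low score indicates condition" marker
#'
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' scores; a patient is called positive (e.g. ARC) when the score falls
#' below the cutoff (low trough-to-peak ratios indicate augmented
#' clearance). The returned cutoff maximises Youden's J = sensitivity +
#' specificity - 1, with ties broken toward higher specificity, then the
#' smaller cutoff.
#'
#' @param scores Numeric marker values (e.g. Cmin/Cmax ratios).
#' @param condition Logical vector: TRUE for condition-positive patients.
#' @return An `fd_roc`: `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   and `curve` (data frame `cutoff`, `fpr`, `tpr`).
#' @export
roc_cutoff <- function(scores, condition) {
  stopifnot(length(scores) == length(condition))
  condition <- as.logical(condition)
  if (!any(condition) || all(condition))
    stop("both classes must be represented", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("scores are constant", call. = FALSE)
  cand <- (u[-1L] + u[-length(u)]) / 2
  npos <- sum(condition); nneg <- sum(!condition)
  tpr <- vapply(cand, function(c) sum(scores[condition] < c) / npos,
                numeric(1))
  fpr <- vapply(cand, function(c) sum(scores[!condition] < c) / nneg,
                numeric(1))
  j <- tpr - fpr
  spec <- 1 - fpr
  # max J; ties -> higher specificity, then smaller cutoff
  best <- order(-j, -spec, cand)[1L]
  structure(list(cutoff = cand[best], sensitivity = tpr[best],
                 specificity = spec[best], youden_j = j[best],
                 curve = data.frame(cutoff = cand, fpr = fpr, tpr = tpr)),
            class = "fd_roc")
}

#' @export
print.fd_roc <- function(x, ...) {
  cat(sprintf("<ROC> cutoff %.4g: sensitivity %.2f, specificity %.2f (J = %.2f)\n",
              x$cutoff, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Cumulative distribution analysis of a marker by condition
#'
#' Empirical cumulative distribution functions for the two groups on a
#' shared grid, plus the location where their vertical distance is largest
#' (which coincides with the Youden-optimal ROC cutoff for the
#' "positive below cutoff" construction).
#'
#' @inheritParams roc_cutoff
#' @return An `fd_cda`: `grid`, `ecdf_positive`, `ecdf_negative`,
#'   `max_distance`, `cutoff`.
#' @export
cda_curves <- function(scores, condition) {
  stopifnot(length(scores) == length(condition))
  condition <- as.logical(condition)
  if (!any(condition) || all(condition))
    stop("both classes must be represented", call. = FALSE)
  grid <- sort(unique(scores))
  Fp <- stats::ecdf(scores[condition])
  Fn <- stats::ecdf(scores[!condition])
  ep <- Fp(grid); en <- Fn(grid)
  d <- ep - en
  # the Youden cutoff uses strict "<": distance just below the next unique
  # score equals the ECDF difference at the current one, so report the
  # midpoint above the maximising score
  i <- which.max(d)
  cutoff <- if (i < length(grid)) (grid[i] + grid[i + 1L]) / 2 else grid[i]
  structure(list(grid = grid, ecdf_positive = ep, ecdf_negative = en,
                 max_distance = max(d), cutoff = cutoff),
            class = "fd_cda")
}

.med_iqr <- function(v) {
  q <- stats::quantile(v, c(.5, .25, .75), na.rm = TRUE, names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[1L], q[2L], q[3L])
}

#' Cohort summary tables
#'
#' Per-drug summaries in the style of a clinical characteristics table plus
#' an exposure/attainment table: median (IQR) covariates, regimen counts,
#' attainment proportions, observed trough by eGFR group, and the overlap
#' of suspected ARC with non-attainment.
#'
#' @param cohort An `fd_cohort` (see [generate_cohort()]) or a list with
#'   `patients` (covariate data frame incl. `drug`), `renal` (data frame
#'   from renal assessments) and `exposure` (data frame of exposure rows).
#' @return A list of data frames: `covariates`, `regimens`, `attainment`,
#'   `cmin_by_egfr`.
#' @export
summarize_cohort <- function(cohort) {
  pts <- cohort$patients
  renal <- cohort$renal
  expo <- cohort$exposure
  stopifnot(nrow(pts) > 0)
  drugs <- unique(pts$drug)
  cov_tab <- do.call(rbind, lapply(drugs, function(d) {
    i <- pts$drug == d
    ri <- renal[renal$patient_id %in% pts$patient_id[i], , drop = FALSE]
    data.frame(drug = d, n = sum(i),
               age = .med_iqr(pts$age_y[i]),
               weight = .med_iqr(pts$weight_kg[i]),
               height = .med_iqr(pts$height_cm[i]),
               creatinine = .med_iqr(pts$creatinine_umol_L[i]),
               relative_egfr = .med_iqr(ri$relative_egfr),
               crcl = .med_iqr(ri$crcl),
               arc_n = sum(ri$arc),
               suspected_arc_n = sum(ri$suspected_arc),
               trauma_n = sum(pts$trauma[i] == 1))
  }))
  reg_tab <- do.call(rbind, lapply(drugs, function(d) {
    i <- pts$drug == d
    lab <- sprintf("%g g + %g g q%gh", pts$loading_mg[i] / 1000,
                   pts$maintenance_mg[i] / 1000, pts$tau_h[i])
    tt <- sort(table(lab), decreasing = TRUE)
    data.frame(drug = d, regimen = names(tt), n = as.integer(tt),
               pct = round(100 * as.integer(tt) / sum(i)))
  }))
  att_tab <- do.call(rbind, lapply(drugs, function(d) {
    e <- expo[expo$drug == d, , drop = FALSE]
    ri <- renal[match(e$patient_id, renal$patient_id), , drop = FALSE]
    non <- !e$attained_100
    data.frame(drug = d, n = nrow(e),
               non_attained_pred_n = sum(non),
               non_attained_pred_pct = round(100 * mean(non)),
               non_attained_obs_n = sum(!e$attained_100_observed,
                                        na.rm = TRUE),
               median_ft_interval_nonattain =
                 if (any(non)) stats::median(e$ft_above_interval[non])
                 else NA_real_,
               median_ft_24h_nonattain =
                 if (any(non)) stats::median(e$ft_above_24h[non])
                 else NA_real_,
               nonattain_with_suspected_arc_n =
                 sum(non & ri$suspected_arc),
               nonattain_egfr_above90_n =
                 sum(non & ri$egfr_group == "above_90"))
  }))
  cmin_tab <- do.call(rbind, lapply(drugs, function(d) {
    e <- expo[expo$drug == d, , drop = FALSE]
    ri <- renal[match(e$patient_id, renal$patient_id), , drop = FALSE]
    hi <- ri$egfr_group == "above_90"
    data.frame(drug = d,
               egfr_group = c("above_90", "at_or_below_90"),
               n = c(sum(hi), sum(!hi)),
               median_cmin_observed = c(
                 stats::median(e$cmin_observed[hi], na.rm = TRUE),
                 stats::median(e$cmin_observed[!hi], na.rm = TRUE)),
               median_half_life = c(
                 stats::median(e$terminal_half_life[hi]),
                 stats::median(e$terminal_half_life[!hi])))
  }))
  list(covariates = cov_tab, regimens = reg_tab, attainment = att_tab,
       cmin_by_egfr = cmin_tab)
}
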