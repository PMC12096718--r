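#' Patient covariates
#'
#' Construct and validate the covariate record used by the renal-function
#' estimators and the population PK covariate models.
#'
#' @param patient_id Identifier (coerced to character).
#' @param age Age in years (> 0, < 140).
#' @param sex `"male"` or `"female"`.
#' @param weight Actual body weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @param serum_creatinine Plasma creatinine in umol/L (> 0).
#' @param sofa Sequential organ failure assessment score (integer >= 0).
#' @param trauma_admission Logical; admitted for trauma.
#'
#' @return An object of class `fd_covariates` (a named list).
#' @export
#' @examples
#' patient_covariates("P01", age = 58, sex = "male", weight = 83,
#'                    height = 178, serum_creatinine = 58, sofa = 8,
#'                    trauma_admission = TRUE)
patient_covariates <- function(patient_id, age, sex, weight, height,
                               serum_creatinine, sofa = 0L,
                               trauma_admission = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  for (nm in c("age", "weight", "height", "serum_creatinine")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  if (age >= 140) stop("'age' must be < 140 years", call. = FALSE)
  sofa <- as.integer(sofa)
  if (is.na(sofa) || sofa < 0L) stop("'sofa' must be a non-negative integer",
                                     call. = FALSE)
  structure(list(patient_id = as.character(patient_id), age = age, sex = sex,
                 weight = weight, height = height,
                 serum_creatinine = serum_creatinine, sofa = sofa,
                 trauma_admission = isTRUE(trauma_admission)),
            class = "fd_covariates")
}

#' @export
print.fd_covariates <- function(x, ...) {
  cat(sprintf("<patient %s> %s, %g y, %g kg, %g cm, SCr %g umol/L, SOFA %d%s\n",
              x$patient_id, x$sex, x$age, x$weight, x$height,
              x$serum_creatinine, x$sofa,
              if (x$trauma_admission) ", trauma" else ""))
  invisible(x)
}

# umol/L -> mg/dL conversion for creatinine
.SCR_UMOL_PER_MGDL <- 88.42

#' Relative eGFR by the race-free CKD-EPI 2021 creatinine equation
#'
#' @param cov An `fd_covariates` object, or missing if `age`, `sex`,
#'   `serum_creatinine` are given directly.
#' @param age Years.
#' @param sex `"male"` or `"female"`.
#' @param serum_creatinine umol/L.
#' @return Estimated GFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' relative_egfr_ckdepi2021(age = 40, sex = "female", serum_creatinine = 61.9)
relative_egfr_ckdepi2021 <- function(cov, age = cov$age, sex = cov$sex,
                                     serum_creatinine = cov$serum_creatinine) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.finite(serum_creatinine) || serum_creatinine <= 0)
    stop("serum creatinine must be positive", call. = FALSE)
  scr <- serum_creatinine / .SCR_UMOL_PER_MGDL
  kappa <- if (sex == "female") 0.7 else 0.9
  alpha <- if (sex == "female") -0.241 else -0.302
  egfr <- 142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.200) *
    0.9938^age
  if (sex == "female") egfr <- egfr * 1.012
  egfr
}

#' Body surface area by the Du Bois formula
#'
#' @param height cm (> 0).
#' @param weight kg (> 0).
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(height, weight) {
  if (!is.finite(height) || height <= 0 || !is.finite(weight) || weight <= 0)
    stop("height and weight must be positive", call. = FALSE)
  0.007184 * height^0.725 * weight^0.425
}

#' Absolute eGFR from relative eGFR and body surface area
#'
#' @param relative_egfr mL/min/1.73 m^2.
#' @param bsa m^2.
#' @return eGFR in mL/min.
#' @export
absolute_egfr <- function(relative_egfr, bsa) {
  if (!is.finite(relative_egfr) || relative_egfr <= 0 ||
      !is.finite(bsa) || bsa <= 0)
    stop("inputs must be positive", call. = FALSE)
  relative_egfr * bsa / 1.73
}

#' Creatinine clearance by Cockcroft-Gault
#'
#' Uses actual body weight and returns the absolute (not BSA-normalised)
#' clearance.
#'
#' @inheritParams relative_egfr_ckdepi2021
#' @param weight kg.
#' @return CrCL in mL/min.
#' @export
crcl_cockcroft_gault <- function(cov, age = cov$age, sex = cov$sex,
                                 weight = cov$weight,
                                 serum_creatinine = cov$serum_creatinine) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(serum_creatinine) || serum_creatinine <= 0)
    stop("serum creatinine must be positive", call. = FALSE)
  if (!is.finite(age) || age <= 0 || age >= 140)
    stop("age must be in (0, 140) years", call. = FALSE)
  scr <- serum_creatinine / .SCR_UMOL_PER_MGDL
  crcl <- (140 - age) * weight / (72 * scr)
  if (sex == "female") crcl <- crcl * 0.85
  crcl
}

#' Default ARC score point table
#'
#' Points identifying patients at risk of augmented renal clearance:
#' young age (<= 50 years) scores 6, trauma admission 3, and a low
#' SOFA score (<= 4) 1 point; maximum 10.
#'
#' @return A list with elements `age_max`, `age_points`, `trauma_points`,
#'   `sofa_max`, `sofa_points`.
#' @export
arc_score_table <- function() {
  list(age_max = 50, age_points = 6L,
       trauma_points = 3L,
       sofa_max = 4, sofa_points = 1L)
}

#' ARC risk score
#'
#' @param cov An `fd_covariates` object, or missing if components given.
#' @param age Years.
#' @param trauma_admission Logical.
#' @param sofa Integer >= 0.
#' @param table Point table, see [arc_score_table()].
#' @return Integer score (points).
#' @export
arc_score <- function(cov, age = cov$age,
                      trauma_admission = cov$trauma_admission,
                      sofa = cov$sofa, table = arc_score_table()) {
  if (sofa < 0) stop("sofa must be >= 0", call. = FALSE)
  s <- 0L
  if (age <= table$age_max) s <- s + table$age_points
  if (isTRUE(trauma_admission)) s <- s + table$trauma_points
  if (sofa <= table$sofa_max) s <- s + table$sofa_points
  s
}

#' Classify augmented renal clearance
#'
#' ARC is defined as estimated CrCL > 130 mL/min. "Suspected ARC" is either
#' CrCL > 130 mL/min, or CrCL > 90 mL/min combined with an elevated ARC
#' score (> 6 points).
#'
#' @param crcl Cockcroft-Gault creatinine clearance, mL/min (>= 0).
#' @param score ARC score, points.
#' @return A list with logical elements `arc` and `suspected_arc`.
#' @export
classify_arc <- function(crcl, score) {
  if (!is.finite(crcl) || crcl < 0) stop("crcl must be >= 0", call. = FALSE)
  arc <- crcl > 130
  list(arc = arc, suspected_arc = arc || (crcl > 90 && score > 6))
}

#' Full renal assessment for one patient
#'
#' @param cov An `fd_covariates` object.
#' @param arc_table ARC point table.
#' @return An `fd_renal` list: `relative_egfr`, `bsa`, `absolute_egfr`,
#'   `crcl`, `arc_score`, `arc`, `suspected_arc`, `egfr_group`
#'   (`"above_90"` / `"at_or_below_90"` on the relative eGFR scale).
#' @export
renal_assessment <- function(cov, arc_table = arc_score_table()) {
  rel <- relative_egfr_ckdepi2021(cov)
  bsa <- bsa_dubois(cov$height, cov$weight)
  abs_egfr <- absolute_egfr(rel, bsa)
  crcl <- crcl_cockcroft_gault(cov)
  sc <- arc_score(cov, table = arc_table)
  cls <- classify_arc(crcl, sc)
  structure(list(patient_id = cov$patient_id,
                 relative_egfr = rel, bsa = bsa, absolute_egfr = abs_egfr,
                 crcl = crcl, arc_score = sc, arc = cls$arc,
                 suspected_arc = cls$suspected_arc,
                 egfr_group = if (rel > 90) "above_90" else "at_or_below_90"),
            class = "fd_renal")
}

#' @export
print.fd_renal <- function(x, ...) {
  cat(sprintf(paste0("<renal %s> eGFR %.1f mL/min/1.73m2 (abs %.1f), ",
                     "CrCL %.1f mL/min, ARC score %d%s\n"),
              x$patient_id, x$relative_egfr, x$absolute_egfr, x$crcl,
              x$arc_score,
              if (x$arc) ", ARC" else if (x$suspected_arc)
                ", suspected ARC" else ""))
  invisible(x)
}

#' Creatinine timeline
#'
#' @param time Hours from admission, strictly increasing.
#' @param serum_creatinine umol/L, all > 0.
#' @param baseline Baseline creatinine umol/L; defaults to the earliest value.
#' @param urine_output Optional data frame with columns `duration` (hours) and
#'   `rate` (mL/kg/h) describing sustained urine-output episodes.
#' @return An `fd_creatinine_timeline` list.
#' @export
creatinine_timeline <- function(time, serum_creatinine, baseline = NULL,
                                urine_output = NULL) {
  if (length(time) != length(serum_creatinine) || length(time) < 1L)
    stop("time and serum_creatinine must be non-empty and equal length",
         call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing",
                                 call. = FALSE)
  if (any(serum_creatinine <= 0)) stop("creatinine values must be positive",
                                       call. = FALSE)
  if (is.null(baseline)) baseline <- serum_creatinine[1L]
  structure(list(time = time, serum_creatinine = serum_creatinine,
                 baseline = baseline, urine_output = urine_output),
            class = "fd_creatinine_timeline")
}

#' KDIGO acute kidney injury classification
#'
#' AKI if any of: creatinine rise >= 26.5 umol/L within 48 h; rise to
#' >= 1.5 x baseline within 7 days; urine output <= 0.5 mL/kg/h sustained
#' for >= 6 h.
#'
#' @param tl An `fd_creatinine_timeline`.
#' @param weight kg (unused by the creatinine criteria; kept for the
#'   urine-output convention of mL/kg/h rates, which are already normalised).
#' @return A list with `aki` (logical) and `criteria` (character vector of
#'   fired criteria among `"delta_48h"`, `"ratio_7d"`, `"oliguria"`).
#' @export
kdigo_aki <- function(tl, weight = NULL) {
  stopifnot(inherits(tl, "fd_creatinine_timeline"))
  fired <- character(0)
  t <- tl$time; s <- tl$serum_creatinine
  n <- length(t)
  # pairwise rise >= 26.5 umol/L within any 48 h span
  for (i in seq_len(n)) {
    j <- which(t > t[i] & t - t[i] <= 48)
    if (length(j) && any(s[j] - s[i] >= 26.5)) {
      fired <- c(fired, "delta_48h"); break
    }
  }
  if (is.null(tl$baseline)) {
    if (length(fired) == 0L)
      stop("baseline creatinine undefined: ratio criterion not evaluable",
           call. = FALSE)
  } else {
    within_week <- t - t[1L] <= 168
    if (any(s[within_week] >= 1.5 * tl$baseline))
      fired <- c(fired, "ratio_7d")
  }
  uo <- tl$urine_output
  if (!is.null(uo) && nrow(uo) > 0 &&
      any(uo$duration >= 6 & uo$rate <= 0.5))
    fired <- c(fired, "oliguria")
  list(aki = length(fired) > 0L, criteria = fired)
}
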