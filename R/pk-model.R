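#' Structural two-compartment parameters
#'
#' @param CL Clearance, L/h (> 0).
#' @param V1 Central volume, L (> 0).
#' @param Q Inter-compartmental clearance, L/h (>= 0; 0 degenerates to a
#'   one-compartment model).
#' @param V2 Peripheral volume, L (> 0 when `Q > 0`).
#' @return An `fd_params` list with micro-constants `k10`, `k12`, `k21`.
#' @export
structural_params <- function(CL, V1, Q = 0, V2 = 0) {
  stopifnot(is.finite(CL), CL > 0, is.finite(V1), V1 > 0,
            is.finite(Q), Q >= 0, is.finite(V2), V2 >= 0)
  if (Q > 0 && V2 <= 0)
    stop("V2 must be positive when Q > 0", call. = FALSE)
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2,
                 k10 = CL / V1,
                 k12 = Q / V1,
                 k21 = if (Q > 0) Q / V2 else 0),
            class = "fd_params")
}

#' @export
print.fd_params <- function(x, ...) {
  cat(sprintf("<PK params> CL %.3g L/h, V1 %.3g L, Q %.3g L/h, V2 %.3g L\n",
              x$CL, x$V1, x$Q, x$V2))
  invisible(x)
}

#' Population pharmacokinetic model
#'
#' Typical parameter values, covariate effects, log-normal between-subject
#' variability and a combined residual-error model
#' (sd = `error_additive` + `error_proportional` * prediction).
#'
#' @param drug Drug label.
#' @param typical An `fd_params` (or list with CL, V1, Q, V2) of typical
#'   values.
#' @param covariate_effects A data frame with columns `parameter`
#'   (CL/V1/Q/V2), `covariate` (name understood by
#'   [individual_parameters()]), `form` (`"power"` or `"proportional"`),
#'   `coefficient`, `reference`. May be `NULL` (no covariates).
#' @param omega Named numeric vector of log-normal standard deviations for a
#'   subset of CL, V1, Q, V2; entries must be >= 0.
#' @param error_additive mg/L (>= 0).
#' @param error_proportional Unitless (>= 0). At least one error component
#'   must be positive.
#' @return An `fd_pop_model`.
#' @export
pop_model <- function(drug, typical, covariate_effects = NULL,
                      omega = c(CL = 0.3, V1 = 0.3),
                      error_additive = 0.1, error_proportional = 0.1) {
  drug <- match.arg(drug, c("meropenem", "piperacillin"))
  if (!inherits(typical, "fd_params"))
    typical <- structural_params(typical$CL, typical$V1,
                                 typical$Q %||% 0, typical$V2 %||% 0)
  if (!is.null(covariate_effects)) {
    covariate_effects <- as.data.frame(covariate_effects)
    stopifnot(all(c("parameter", "covariate", "form", "coefficient",
                    "reference") %in% names(covariate_effects)),
              all(covariate_effects$form %in% c("power", "proportional")))
  }
  stopifnot(length(omega) >= 1L, !is.null(names(omega)),
            all(names(omega) %in% c("CL", "V1", "Q", "V2")),
            all(omega >= 0))
  if (error_additive < 0 || error_proportional < 0 ||
      (error_additive == 0 && error_proportional == 0))
    stop("residual error model needs a positive additive and/or proportional component",
         call. = FALSE)
  structure(list(drug = drug, typical = typical,
                 covariate_effects = covariate_effects, omega = omega,
                 error_additive = error_additive,
                 error_proportional = error_proportional),
            class = "fd_pop_model")
}

#' @export
print.fd_pop_model <- function(x, ...) {
  cat(sprintf("<popPK model: %s> CL %.3g, V1 %.3g, Q %.3g, V2 %.3g L(/h)\n",
              x$drug, x$typical$CL, x$typical$V1, x$typical$Q, x$typical$V2))
  if (!is.null(x$covariate_effects))
    cat("  covariates:",
        paste(sprintf("%s~%s(%s)", x$covariate_effects$parameter,
                      x$covariate_effects$covariate,
                      x$covariate_effects$form), collapse = ", "), "\n")
  cat(sprintf("  omega: %s; error a=%g mg/L, b=%g\n",
              paste(sprintf("%s=%.2g", names(x$omega), x$omega),
                    collapse = ", "),
              x$error_additive, x$error_proportional))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a population model from a YAML configuration file
#'
#' @param path Path to a YAML file with fields `drug`, `typical`
#'   (CL/V1/Q/V2), optional `covariate_effects` (list of records), `omega`
#'   (named), `error` (`additive`, `proportional`).
#' @return An `fd_pop_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cov <- NULL
  if (!is.null(cfg$covariate_effects) && length(cfg$covariate_effects))
    cov <- do.call(rbind, lapply(cfg$covariate_effects, as.data.frame))
  pop_model(drug = cfg$drug,
            typical = structural_params(cfg$typical$CL, cfg$typical$V1,
                                        cfg$typical$Q %||% 0,
                                        cfg$typical$V2 %||% 0),
            covariate_effects = cov,
            omega = unlist(cfg$omega),
            error_additive = cfg$error$additive,
            error_proportional = cfg$error$proportional)
}

#' Bundled default population models
#'
#' Returns the package's default population PK model for a drug, read from
#' the YAML configurations shipped under `inst/models/`. The defaults follow
#' the structure used in the analysis: a two-compartment meropenem model with
#' creatinine clearance and age as covariates on CL and body weight on V1,
#' and a covariate-free two-compartment piperacillin model.
#'
#' @param drug `"meropenem"` or `"piperacillin"`.
#' @return An `fd_pop_model`.
#' @export
default_model <- function(drug = c("meropenem", "piperacillin")) {
  drug <- match.arg(drug)
  read_model_config(system.file("models", paste0(drug, ".yml"),
                                package = "firstdose", mustWork = TRUE))
}

#' Individual parameters from covariates and random effects
#'
#' parameter_i = typical_i * covariate multipliers * exp(eta_i). Power
#' effects contribute `(x / reference)^coefficient`, proportional effects
#' `1 + coefficient * (x - reference)`.
#'
#' @param pop An `fd_pop_model`.
#' @param cov An `fd_covariates` (may be `NULL` for covariate-free models).
#' @param crcl Cockcroft-Gault creatinine clearance, mL/min (required when
#'   the model has a `crcl` covariate effect).
#' @param eta Named (or omega-ordered) numeric vector of random effects; 0
#'   for parameters without variability.
#' @return An `fd_params`.
#' @export
individual_parameters <- function(pop, cov = NULL, crcl = NULL,
                                  eta = numeric(0)) {
  stopifnot(inherits(pop, "fd_pop_model"))
  th <- c(CL = pop$typical$CL, V1 = pop$typical$V1,
          Q = pop$typical$Q, V2 = pop$typical$V2)
  ce <- pop$covariate_effects
  if (!is.null(ce)) {
    for (i in seq_len(nrow(ce))) {
      x <- switch(ce$covariate[i],
                  crcl = crcl,
                  age = cov$age,
                  weight = cov$weight,
                  height = cov$height,
                  stop("unknown covariate '", ce$covariate[i], "'",
                       call. = FALSE))
      if (is.null(x) || !is.finite(x))
        stop("covariate '", ce$covariate[i],
             "' required by the model but missing", call. = FALSE)
      mult <- switch(ce$form[i],
                     power = (x / ce$reference[i])^ce$coefficient[i],
                     proportional = 1 + ce$coefficient[i] *
                       (x - ce$reference[i]))
      th[ce$parameter[i]] <- th[ce$parameter[i]] * mult
    }
  }
  if (length(eta)) {
    if (is.null(names(eta))) {
      if (length(eta) != length(pop$omega))
        stop("eta dimension must match omega", call. = FALSE)
      names(eta) <- names(pop$omega)
    }
    th[names(eta)] <- th[names(eta)] * exp(eta)
  }
  structural_params(th[["CL"]], th[["V1"]], th[["Q"]], th[["V2"]])
}

#' Residual error standard deviation (combined model)
#'
#' sd = a + b * prediction.
#'
#' @param pred Predicted concentration, mg/L (>= 0).
#' @param pop An `fd_pop_model`.
#' @return mg/L.
#' @export
residual_sd <- function(pred, pop) {
  stopifnot(all(pred >= 0))
  pop$error_additive + pop$error_proportional * pred
}
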