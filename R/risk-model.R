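#' Clinical risk-factor model
#'
#' Container for the log relative risks ("beta coefficients") of the six
#' dichotomous clinical risk factors (prior fragility fracture, parental
#' hip fracture, current smoking, oral glucocorticoids, rheumatoid
#' arthritis, alcohol excess), their population prevalences, the femoral
#' neck BMD gradient of risk, and the BMI effect used when BMD is absent.
#'
#' @param crfs data.frame with columns `name`, `log_rr_fracture`,
#'   `log_rr_death`, `prevalence` and one row per clinical risk factor.
#' @param gradient_hip,gradient_mof gradient of risk: relative risk of the
#'   outcome per SD decrease in femoral-neck T-score (> 0).
#' @param bmi_log_rr_per_unit log relative risk of fracture per kg/m^2 of
#'   BMI above 25, applied only when no T-score is supplied (low BMI raises
#'   risk, so the default is negative).
#' @param tscore_mean_slope change of the population-mean T-score per year
#'   of age after 50; the age-conditional T-score distribution used to
#'   integrate the BMD term is Normal(mean = slope * (age - 50), sd = 1).
#' @return object of class `risk_factor_model`.
#' @export
risk_factor_model <- function(crfs,
                              gradient_hip = 2.0,
                              gradient_mof = 1.6,
                              bmi_log_rr_per_unit = -0.05,
                              tscore_mean_slope = -0.045) {
  need <- c("name", "log_rr_fracture", "log_rr_death", "prevalence")
  stop_if_not(all(need %in% names(crfs)),
              "crfs must have columns name, log_rr_fracture, log_rr_death, prevalence")
  stop_if_not(all(crfs$prevalence >= 0 & crfs$prevalence <= 1),
              "prevalences must lie in [0, 1]")
  stop_if_not(gradient_hip > 0 && gradient_mof > 0,
              "gradients of risk must be positive")
  structure(list(crfs = crfs,
                 gradient_hip = gradient_hip,
                 gradient_mof = gradient_mof,
                 bmi_log_rr_per_unit = bmi_log_rr_per_unit,
                 tscore_mean_slope = tscore_mean_slope),
            class = "risk_factor_model")
}

#' Draw a synthetic clinical risk-factor model
#'
#' Stands in for unpublished country-specific beta coefficients: each of the
#' six binary risk factors gets a fracture relative risk drawn uniformly (on
#' the RR scale) in \[1.2, 2.5\], a death relative risk in \[1.0, 1.8\] and a
#' prevalence in \[0.02, 0.35\]; the hip gradient of risk per SD is drawn in
#' \[1.4, 2.6\] and the MOF gradient in \[1.3, 1.9\]. Risk factors are
#' mutually independent.
#'
#' @param seed integer RNG seed; a fixed seed reproduces the model exactly.
#' @return a [risk_factor_model()].
#' @export
generate_risk_factor_model <- function(seed = 1L) {
  with_seed(seed, {
    crfs <- data.frame(
      name = CRF_NAMES,
      log_rr_fracture = log(runif(6, 1.2, 2.5)),
      log_rr_death = log(runif(6, 1.0, 1.8)),
      prevalence = runif(6, 0.02, 0.35),
      stringsAsFactors = FALSE)
    risk_factor_model(crfs,
                      gradient_hip = runif(1, 1.4, 2.6),
                      gradient_mof = runif(1, 1.3, 1.9))
  })
}

#' Null risk-factor model (all effects switched off)
#'
#' All log relative risks zero and unit gradients; every profile then has
#' relative risk 1, so calibrated baselines equal observed rates.
#'
#' @param prevalence prevalence assigned to each risk factor.
#' @return a [risk_factor_model()].
#' @export
null_risk_factor_model <- function(prevalence = 0.1) {
  risk_factor_model(
    data.frame(name = CRF_NAMES, log_rr_fracture = 0, log_rr_death = 0,
               prevalence = prevalence, stringsAsFactors = FALSE),
    gradient_hip = 1, gradient_mof = 1, bmi_log_rr_per_unit = 0)
}

gradient_for <- function(model, outcome) {
  switch(outcome, hip = model$gradient_hip, mof = model$gradient_mof,
         stop("no BMD gradient for outcome ", outcome))
}

# E[g^(-T)] with T ~ Normal(mu(age), 1): lognormal mean
bmd_mean_rr <- function(model, age, outcome) {
  g <- gradient_for(model, outcome)
  mu <- model$tscore_mean_slope * (age - 50)
  exp(-log(g) * mu + log(g)^2 / 2)
}

#' Population-mean relative risk at an age
#'
#' The expectation of the individual relative risk over the population
#' distribution of risk factors: for independent binary factors,
#' \eqn{\prod_c (1 - p_c + p_c e^{\beta_c})}; for fracture outcomes this is
#' multiplied by the BMD term integrated over the age-conditional Normal
#' T-score distribution. This is the calibration constant that links the
#' baseline hazard to the observed population rate.
#'
#' @param model a [risk_factor_model()].
#' @param age age in years.
#' @param sex `"male"` or `"female"` (prevalences are shared by default but
#'   the argument fixes the signature for age/sex-specific extensions).
#' @param outcome `"hip"`, `"mof"` or `"death"`.
#' @return population-mean relative risk (>= 0).
#' @export
population_mean_rr <- function(model, age, sex = "female",
                               outcome = c("hip", "mof", "death")) {
  outcome <- match.arg(outcome)
  beta <- if (outcome == "death") model$crfs$log_rr_death else
    model$crfs$log_rr_fracture
  p <- model$crfs$prevalence
  crf_term <- prod(1 - p + p * exp(beta))
  if (outcome == "death") crf_term else
    crf_term * bmd_mean_rr(model, age, outcome)
}

#' Construct an individual risk profile
#'
#' @param age age in years (40-90).
#' @param sex `"male"` or `"female"`.
#' @param bmi body-mass index, kg/m^2 (15-45).
#' @param crfs character vector naming the risk factors present (subset of
#'   `prior_fracture`, `parent_hip_fracture`, `smoking`, `glucocorticoids`,
#'   `rheumatoid_arthritis`, `alcohol`), or a named logical/0-1 vector.
#' @param tscore femoral-neck T-score, or `NULL` when BMD is not measured
#'   (the BMD term is then integrated out and the BMI effect applies).
#' @return one-row data.frame in the layout [predict.frax_model()] accepts.
#' @export
risk_profile <- function(age, sex, bmi = 25, crfs = character(), tscore = NULL) {
  stop_if_not(age >= 40 && age <= 90, "age must be in [40, 90]")
  stop_if_not(bmi >= 15 && bmi <= 45, "BMI must be in [15, 45]")
  if (!is.null(tscore))
    stop_if_not(tscore >= -5 && tscore <= 2, "T-score must be in [-5, 2]")
  x <- setNames(rep(0L, length(CRF_NAMES)), CRF_NAMES)
  if (is.character(crfs)) {
    stop_if_not(all(crfs %in% CRF_NAMES), "unknown risk factor name")
    x[crfs] <- 1L
  } else {
    x[names(crfs)] <- as.integer(crfs)
  }
  out <- data.frame(age = age, sex = match.arg(sex, SEXES), bmi = bmi,
                    tscore = if (is.null(tscore)) NA_real_ else tscore)
  out[CRF_NAMES] <- as.list(x)
  out
}
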