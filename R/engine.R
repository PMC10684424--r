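# hazard lookup scaffolding: band tables are interpolated log-linearly at
# integer ages; a piecewise incidence fit is evaluated directly.
rate_at_ages <- function(x, ages, sex) {
  if (inherits(x, "piecewise_incidence"))
    return(predict_rate(x, pmin(ages, 110), sex))
  d <- x[x$sex == sex, ]
  stop_if_not(nrow(d) >= 2, "need at least two bands per sex")
  mid <- band_midpoint(d$age_lo, d$age_hi)
  if (all(d$rate == 0)) return(rep(0, length(ages)))
  if (any(d$rate <= 0))  # zeros preclude the log scale; fall back to linear
    return(pmax(0, approx(mid, d$rate, xout = ages, rule = 2)$y))
  exp(approx(mid, log(d$rate), xout = ages, rule = 2)$y)
}

#' Calibrate a fracture-probability model to population rates
#'
#' Builds the runnable country model: for each sex and integer age 50-110,
#' the baseline hip, MOF and death hazards are the observed population
#' hazards divided by the population-mean relative risk at that age
#' ([population_mean_rr()]), so that the population average of the
#' individual hazards reproduces the input incidence and mortality exactly
#' while leaving the relative importance of the beta coefficients
#' untouched (proportional-hazards calibration).
#'
#' @param incidence_hip hip incidence: a band rate table (`sex`, `age_lo`,
#'   `age_hi`, `rate` per 100,000) or a [fit_piecewise_loglinear()] result.
#' @param incidence_mof combined first-MOF incidence in the same forms (the
#'   `site == "mof"` rows of [impute_mof_rates()] output work directly).
#' @param life_table data.frame (`sex`, `age`, `hazard`) for integer ages
#'   covering 50-110, e.g. [generate_life_table()].
#' @param model a [risk_factor_model()].
#' @return object of class `frax_model`: per-sex hazard tables
#'   (`age`, `h0_hip`, `h0_mof`, `h0_death`, observed hazards and the
#'   calibration constants), plus the embedded risk-factor model.
#' @export
calibrate <- function(incidence_hip, incidence_mof, life_table, model) {
  if (is.data.frame(incidence_mof) && "site" %in% names(incidence_mof))
    incidence_mof <- incidence_mof[incidence_mof$site == "mof",
                                   c("sex", "age_lo", "age_hi", "rate")]
  ages <- 50:110
  haz <- lapply(SEXES, function(s) {
    lt <- life_table[life_table$sex == s, ]
    stop_if_not(all(ages %in% lt$age), "life table must cover ages 50-110")
    obs_hip <- rate_at_ages(incidence_hip, ages, s) / 1e5
    obs_mof <- rate_at_ages(incidence_mof, ages, s) / 1e5
    obs_d <- lt$hazard[match(ages, lt$age)]
    c_hip <- vapply(ages, population_mean_rr, numeric(1),
                    model = model, sex = s, outcome = "hip")
    c_mof <- vapply(ages, population_mean_rr, numeric(1),
                    model = model, sex = s, outcome = "mof")
    c_d <- vapply(ages, population_mean_rr, numeric(1),
                  model = model, sex = s, outcome = "death")
    if (any(obs_hip == 0 | obs_mof == 0))
      warning("zero observed incidence: baseline hazard set to 0")
    data.frame(age = ages,
               h0_hip = obs_hip / c_hip, h0_mof = obs_mof / c_mof,
               h0_death = obs_d / c_d,
               obs_hip = obs_hip, obs_mof = obs_mof, obs_death = obs_d,
               c_hip = c_hip, c_mof = c_mof, c_death = c_d)
  })
  structure(list(hazards = setNames(haz, SEXES), model = model),
            class = "frax_model")
}

#' Rescale the fracture incidence a model was calibrated to
#'
#' Multiplies the baseline (and observed) hip and MOF hazards by `factor`,
#' leaving death hazards and all relative risks unchanged — the operation
#' behind comparing an original model with an update built on lower
#' observed incidence.
#'
#' @param model a [calibrate()]d model.
#' @param factor positive scale factor.
#' @return a rescaled `frax_model`.
#' @export
scale_incidence <- function(model, factor) {
  stop_if_not(factor > 0, "scale factor must be positive")
  for (s in SEXES) {
    cols <- c("h0_hip", "h0_mof", "obs_hip", "obs_mof")
    model$hazards[[s]][cols] <- model$hazards[[s]][cols] * factor
  }
  model
}

# relative risk of a profile row for one outcome at a given attained age
profile_rr <- function(model, profile, outcome, attained_age) {
  rf <- model$model
  beta <- if (outcome == "death") rf$crfs$log_rr_death else
    rf$crfs$log_rr_fracture
  x <- as.numeric(profile[1, rf$crfs$name])
  rr <- exp(sum(beta * x))
  if (outcome != "death") {
    if (!is.na(profile$tscore[1])) {
      rr <- rr * gradient_for(rf, outcome)^(-profile$tscore[1])
    } else {
      rr <- rr * bmd_mean_rr(rf, attained_age, outcome) *
        exp(rf$bmi_log_rr_per_unit * (profile$bmi[1] - 25))
    }
  }
  rr
}

#' Individual annual hazard under a calibrated model
#'
#' Baseline hazard at the attained age times the profile's relative risk
#' \eqn{\exp(\sum_c \beta_c x_c)} with the BMD term
#' \eqn{g^{-T}} when a T-score is present (gradient of risk `g` per SD
#' decrease), or the population-average BMD term plus the BMI effect when
#' it is absent.
#'
#' @param model a [calibrate()]d `frax_model`.
#' @param profile a [risk_profile()] row.
#' @param outcome `"hip"`, `"mof"` or `"death"`.
#' @param attained_age integer age within the model's 50-110 range.
#' @return hazard per person-year.
#' @export
individual_hazard <- function(model, profile,
                              outcome = c("hip", "mof", "death"),
                              attained_age = profile$age[1]) {
  outcome <- match.arg(outcome)
  h <- model$hazards[[profile$sex[1]]]
  i <- match(attained_age, h$age)
  stop_if_not(all(!is.na(i)), "attained age outside the model's age range")
  h0 <- h[[paste0("h0_", if (outcome == "death") "death" else outcome)]][i]
  h0 * profile_rr(model, profile, outcome, attained_age)
}

# per-year fracture and death hazards over the 10-year horizon
horizon_hazards <- function(model, profile, outcome) {
  ages <- profile$age[1] + 0:9
  list(hf = individual_hazard(model, profile, outcome, ages),
       hd = individual_hazard(model, profile, "death", ages))
}

#' 10-year fracture probability under competing mortality
#'
#' Integrates the fracture hazard against survival from both fracture and
#' death over a 10-year horizon, with hazards held constant within each
#' year of age: with per-year hazards \eqn{h_f(t), h_d(t)},
#' \deqn{P = \sum_{t=0}^{9} S(t) \frac{h_f}{h_f + h_d}
#'       \left(1 - e^{-(h_f + h_d)\Delta}\right) \cdots}
#' accumulated over steps of length \eqn{\Delta} (1 year by default, 1/12
#' with `step = "monthly"`; the two agree analytically because hazards are
#' year-constant, the option exists to expose the discretisation surface).
#'
#' @inheritParams individual_hazard
#' @param outcome `"hip"` or `"mof"`.
#' @param step `"annual"` or `"monthly"` evaluation grid.
#' @return probability in \[0, 1\].
#' @export
ten_year_probability <- function(model, profile, outcome = c("hip", "mof"),
                                 step = c("annual", "monthly")) {
  outcome <- match.arg(outcome)
  step <- match.arg(step)
  hz <- horizon_hazards(model, profile, outcome)
  nsub <- if (step == "annual") 1L else 12L
  delta <- 1 / nsub
  S <- 1
  P <- 0
  for (t in 1:10) {
    H <- hz$hf[t] + hz$hd[t]
    frac <- if (H > 0) hz$hf[t] / H else 0
    for (m in seq_len(nsub)) {
      P <- P + S * frac * (1 - exp(-H * delta))
      S <- S * exp(-H * delta)
    }
  }
  min(max(P, 0), 1)
}

#' Predict 10-year probabilities for a table of profiles
#'
#' @param object a [calibrate()]d `frax_model`.
#' @param newdata data.frame of profiles in the [risk_profile()] layout
#'   (columns `age`, `sex`, `bmi`, `tscore`, one 0/1 column per risk
#'   factor); e.g. a [build_scenario_grid()].
#' @param outcome `"hip"` or `"mof"`.
#' @param step evaluation grid, as in [ten_year_probability()].
#' @param ... unused.
#' @return numeric vector of probabilities, one per row.
#' @export
predict.frax_model <- function(object, newdata, outcome = c("hip", "mof"),
                               step = "annual", ...) {
  outcome <- match.arg(outcome)
  vapply(seq_len(nrow(newdata)), function(i) {
    ten_year_probability(object, newdata[i, , drop = FALSE], outcome, step)
  }, numeric(1))
}

#' Micro-simulation of the 10-year outcome for one profile
#'
#' Discrete-event simulation on a monthly grid: each simulant's first-event
#' time is drawn from the piecewise-constant total hazard (fracture +
#' death, constant within each year of age) by inverting the cumulative
#' hazard, and the event is allocated to fracture with probability
#' \eqn{h_f/(h_f+h_d)} at the event month. Serves as an independent
#' stochastic check on [ten_year_probability()].
#'
#' @param object a [calibrate()]d `frax_model`.
#' @param nsim number of simulants.
#' @param seed integer RNG seed.
#' @param profile a [risk_profile()] row.
#' @param outcome `"hip"` or `"mof"`.
#' @param ... unused.
#' @return list with `p_hat` (fraction fracturing within 10 years), `se`
#'   (binomial Monte-Carlo standard error) and `nsim`.
#' @export
simulate.frax_model <- function(object, nsim = 200000, seed = 1L,
                                profile, outcome = c("hip", "mof"), ...) {
  outcome <- match.arg(outcome)
  hz <- horizon_hazards(object, profile, outcome)
  month_year <- rep(1:10, each = 12)
  Hm <- (hz$hf + hz$hd)[month_year] / 12
  cumH <- c(0, cumsum(Hm))
  frac_p <- ifelse(hz$hf + hz$hd > 0, hz$hf / (hz$hf + hz$hd), 0)
  with_seed(seed, {
    e <- rexp(nsim)
    month <- findInterval(e, cumH, left.open = TRUE)  # 121 => no event
    event <- month <= 120
    fracture <- logical(nsim)
    fracture[event] <-
      runif(sum(event)) < frac_p[month_year[month[event]]]
    p <- mean(fracture)
    list(p_hat = p, se = sqrt(p * (1 - p) / nsim), nsim = nsim)
  })
}

#' @export
print.frax_model <- function(x, ...) {
  cat("Calibrated 10-year fracture-probability model\n")
  cat("  ages 50-110, sexes:", paste(names(x$hazards), collapse = ", "), "\n")
  for (s in names(x$hazards)) {
    h <- x$hazards[[s]]
    i <- match(c(50, 70, 90), h$age)
    cat(sprintf(
      "  %s: hip incidence %.1f/%.1f/%.1f per 100k at 50/70/90; mean RR (hip) %.3f\n",
      s, h$obs_hip[i[1]] * 1e5, h$obs_hip[i[2]] * 1e5, h$obs_hip[i[3]] * 1e5,
      h$c_hip[i[1]]))
  }
  invisible(x)
}

#' @export
summary.frax_model <- function(object, ...) {
  ref <- do.call(rbind, lapply(SEXES, function(s) {
    do.call(rbind, lapply(c(50, 60, 70, 80), function(a) {
      pr <- risk_profile(a, s, tscore = 0)
      data.frame(sex = s, age = a,
                 p_hip = ten_year_probability(object, pr, "hip"),
                 p_mof = ten_year_probability(object, pr, "mof"))
    }))
  }))
  structure(list(reference = ref), class = "summary.frax_model")
}

#' @export
print.summary.frax_model <- function(x, ...) {
  cat("10-year probabilities (%) for a risk-factor-free profile, T-score 0:\n")
  r <- x$reference
  r$p_hip <- sprintf("%.1f", 100 * r$p_hip)
  r$p_mof <- sprintf("%.1f", 100 * r$p_mof)
  print(r, row.names = FALSE)
  invisible(x)
}
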