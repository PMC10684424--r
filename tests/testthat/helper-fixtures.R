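sexes <- c("male", "female")

crf_names <- c("prior_fracture", "parent_hip_fracture", "smoking",
               "glucocorticoids", "rheumatoid_arthritis", "alcohol")

# truth with a flat incidence curve (rate per 100,000 at every age)
flat_truth <- function(rate) {
  seg <- function(knots) list(log_rate_50 = log(rate), knots = knots,
                              slopes = rep(0, length(knots) + 1))
  ground_truth_incidence(male = seg(c(62, 87)), female = seg(c(62, 82)))
}

# band rate table with one constant rate for both sexes
flat_rate_table <- function(rate, which_sexes = sexes) {
  b <- age_bands()
  do.call(rbind, lapply(which_sexes, function(s) {
    data.frame(sex = s, age_lo = b$age_lo, age_hi = b$age_hi, rate = rate,
               stringsAsFactors = FALSE)
  }))
}

# noise-free band rates evaluated from a ground truth
truth_rate_table <- function(truth = ground_truth_incidence()) {
  b <- age_bands()
  do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, age_lo = b$age_lo, age_hi = b$age_hi,
               rate = true_rate(truth, b$midpoint, s),
               stringsAsFactors = FALSE)
  }))
}

const_life_table <- function(hazard) {
  do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, age = 50:110, hazard = hazard,
               stringsAsFactors = FALSE)
  }))
}

both_ratio_tables <- function() {
  rbind(generate_ratio_table("female"), generate_ratio_table("male"))
}

# model with a single binary risk factor and neutral BMD/BMI terms
single_crf_model <- function(p, rr, rr_death = 1) {
  risk_factor_model(
    data.frame(name = "prior_fracture", log_rr_fracture = log(rr),
               log_rr_death = log(rr_death), prevalence = p,
               stringsAsFactors = FALSE),
    gradient_hip = 1, gradient_mof = 1, bmi_log_rr_per_unit = 0,
    tscore_mean_slope = 0)
}

# memoised reference calibration used across test files
.fixtures <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    rates <- truth_rate_table()
    mof <- impute_mof_rates(rates, both_ratio_tables())
    .fixtures$model <- calibrate(rates, mof, generate_life_table(),
                                 generate_risk_factor_model(42))
  }
  .fixtures$model
}

# same calibration but with scenario-independent mortality (zero death
# betas): the regime where incidence rescaling provably preserves ranks
fixture_model_shared_death <- function() {
  if (is.null(.fixtures$model_sd)) {
    rf <- generate_risk_factor_model(42)
    rf$crfs$log_rr_death <- 0
    rates <- truth_rate_table()
    mof <- impute_mof_rates(rates, both_ratio_tables())
    .fixtures$model_sd <- calibrate(rates, mof, generate_life_table(), rf)
  }
  .fixtures$model_sd
}

random_profiles <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    risk_profile(age = sample(50:80, 1),
                 sex = sample(sexes, 1),
                 bmi = runif(1, 20, 32),
                 crfs = sample(crf_names, sample(0:3, 1)),
                 tscore = if (runif(1) < 0.7) runif(1, -3.5, 0) else NULL)
  }))
}
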