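test_that("population-mean relative risk follows the independence product", {
  # single factor: 1 - p + p r
  m1 <- single_crf_model(p = 0.1, rr = 2)
  expect_equal(population_mean_rr(m1, 65, "female", "hip"), 1.1)
  # two factors multiply: (0.9 + 0.2*1.5) ... = 1.1 * 1.075
  m2 <- risk_factor_model(
    data.frame(name = c("prior_fracture", "smoking"),
               log_rr_fracture = log(c(1.5, 2.5)),
               log_rr_death = 0, prevalence = c(0.2, 0.05)),
    gradient_hip = 1, gradient_mof = 1, bmi_log_rr_per_unit = 0,
    tscore_mean_slope = 0)
  expect_equal(population_mean_rr(m2, 65, "female", "hip"), 1.1 * 1.075)
  # null model: exactly 1 for every outcome
  nm <- null_risk_factor_model()
  for (out in c("hip", "mof", "death"))
    expect_equal(population_mean_rr(nm, 70, "male", out), 1)
})

test_that("calibration divides observed rates by the mean relative risk", {
  lt <- generate_life_table()
  hip <- flat_rate_table(110)
  mof <- flat_rate_table(300)

  # null model: baselines equal observed hazards exactly
  m0 <- calibrate(hip, mof, lt, null_risk_factor_model())
  expect_equal(m0$hazards$female$h0_hip, rep(110 / 1e5, 61))
  expect_equal(m0$hazards$male$h0_mof, rep(300 / 1e5, 61))

  # single CRF p = 0.1, RR = 2: observed 110 -> baseline 100 per 100k
  m1 <- calibrate(hip, mof, lt, single_crf_model(0.1, 2))
  expect_equal(m1$hazards$female$h0_hip, rep(100 / 1e5, 61))

  # doubling all incidence doubles baselines, leaves relative risks alone
  hip2 <- hip; hip2$rate <- 2 * hip$rate
  mof2 <- mof; mof2$rate <- 2 * mof$rate
  m2 <- calibrate(hip2, mof2, lt, single_crf_model(0.1, 2))
  expect_equal(m2$hazards$male$h0_hip, 2 * m1$hazards$male$h0_hip)
  expect_equal(m2$hazards$male$c_hip, m1$hazards$male$c_hip)
  expect_equal(scale_incidence(m1, 2)$hazards$male$h0_hip,
               m2$hazards$male$h0_hip)
})

test_that("individual hazards respond to T-score and risk factors", {
  model <- fixture_model()
  g <- model$model$gradient_hip
  p0 <- risk_profile(70, "female", tscore = 0)
  p1 <- risk_profile(70, "female", tscore = -1)
  h0 <- individual_hazard(model, p0, "hip")
  h1 <- individual_hazard(model, p1, "hip")
  expect_equal(h1 / h0, g)
  # T-score 0 leaves only the baseline (BMD-integration convention)
  expect_equal(h0, model$hazards$female$h0_hip[match(70, 50:110)])
  # flipping any risk factor with positive beta raises the hazard
  for (crf in crf_names) {
    pc <- risk_profile(70, "female", crfs = crf, tscore = 0)
    expect_gt(individual_hazard(model, pc, "hip"), h0)
  }
  expect_error(individual_hazard(model, p0, "hip", attained_age = 120),
               "age")
})

test_that("10-year probability matches the zero-mortality closed form", {
  lt0 <- const_life_table(0)
  hip <- flat_rate_table(2000)  # hazard 0.02 per year
  m <- calibrate(hip, flat_rate_table(4000), lt0, null_risk_factor_model())
  pr <- risk_profile(60, "female")
  p_annual <- ten_year_probability(m, pr, "hip", step = "annual")
  expect_lt(abs(p_annual - (1 - exp(-0.2))), 0.002)
  p_monthly <- ten_year_probability(m, pr, "hip", step = "monthly")
  expect_lt(abs(p_monthly - (1 - exp(-0.2))), 0.0002)

  # zero fracture hazard gives probability zero
  mz <- suppressWarnings(
    calibrate(flat_rate_table(0), flat_rate_table(0), const_life_table(0.01),
              null_risk_factor_model()))
  expect_equal(ten_year_probability(mz, pr, "hip"), 0)
})

test_that("competing-risk monotonicity and ordering invariants hold", {
  model <- fixture_model()
  profiles <- random_profiles(12, seed = 31)
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, , drop = FALSE]
    p_hip <- ten_year_probability(model, pr, "hip")
    p_mof <- ten_year_probability(model, pr, "mof")
    expect_gte(p_hip, 0); expect_lte(p_mof, 1)
    expect_lte(p_hip, p_mof)
    # halving fracture incidence strictly lowers the probability
    half <- scale_incidence(model, 0.5)
    expect_lt(ten_year_probability(half, pr, "hip"), p_hip)
    # doubling death hazards cannot raise fracture probability
    deadlier <- model
    for (s in sexes)
      deadlier$hazards[[s]]$h0_death <- 2 * model$hazards[[s]]$h0_death
    expect_lte(ten_year_probability(deadlier, pr, "hip"), p_hip)
  }
  # lower T-score raises probability when the gradient exceeds 1
  pa <- risk_profile(70, "male", tscore = -0.5)
  pb <- risk_profile(70, "male", tscore = -2.5)
  expect_gt(ten_year_probability(model, pb, "hip"),
            ten_year_probability(model, pa, "hip"))
})

test_that("engine agrees with the micro-simulation oracle", {
  model <- fixture_model()
  profiles <- random_profiles(5, seed = 77)
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, , drop = FALSE]
    p <- ten_year_probability(model, pr, "mof")
    sim <- simulate(model, nsim = 30000, seed = 100 + i, profile = pr,
                    outcome = "mof")
    expect_lt(abs(p - sim$p_hat), 3 * sim$se + 1e-12)
  }
})

test_that("model JSON serialisation round-trips predictions", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  pr <- risk_profile(65, "female", crfs = "smoking", tscore = -1.5)
  expect_equal(ten_year_probability(back, pr, "hip"),
               ten_year_probability(model, pr, "hip"))
})
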