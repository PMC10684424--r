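test_that("scenario grid is exhaustive and duplicate-free", {
  g <- build_scenario_grid(ages = c(50, 70), sexes = "female")
  expect_equal(nrow(g), 2 * 512)
  per_cell <- table(g$age)
  expect_true(all(per_cell == 512))
  key <- do.call(paste, g[c("age", "sex", "tscore", crf_names)])
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(g$bmi == 25))
  expect_equal(sort(unique(g$tscore)), seq(-3.5, 0, by = 0.5))
  # (2^6 - 1) x 8 scenarios carry at least one risk factor
  one_cell <- g[g$age == 50, ]
  expect_equal(sum(rowSums(one_cell[crf_names]) >= 1), 504)
  # reduced grid: one factor, one T-score -> 2 scenarios
  tiny <- build_scenario_grid(ages = 60, sexes = "male", tscores = -1,
                              crf_names = "prior_fracture")
  expect_equal(nrow(tiny), 2)
})

test_that("paired probabilities respect self-identity and incidence scaling", {
  model <- fixture_model()
  grid <- build_scenario_grid(ages = 70, sexes = "female")
  self <- pair_probabilities(model, model, grid, "hip")
  expect_equal(nrow(self), 512)
  expect_equal(self$p_original, self$p_updated)
  scaled <- pair_probabilities(model, scale_incidence(model, 0.5),
                               grid, "hip")
  expect_true(all(scaled$p_updated < scaled$p_original))
  # rank preservation: exact with scenario-independent mortality, near-exact
  # when risk factors also raise the death hazard
  expect_gte(agreement_stats(scaled)$spearman, 0.9999)
  sd_model <- fixture_model_shared_death()
  sd_pairs <- pair_probabilities(sd_model, scale_incidence(sd_model, 0.5),
                                 grid, "hip")
  expect_equal(agreement_stats(sd_pairs)$spearman, 1, tolerance = 0)
})

test_that("agreement statistics match direct formulas", {
  id <- data.frame(p_original = c(0.1, 0.2, 0.3), p_updated = c(0.1, 0.2, 0.3))
  expect_equal(agreement_stats(id)$pearson, 1)
  lin <- data.frame(p_original = c(0.1, 0.25, 0.4),
                    p_updated = 0.6 * c(0.1, 0.25, 0.4))
  st <- agreement_stats(lin)
  expect_equal(st$pearson, 1)
  expect_equal(st$spearman, 1)
  # hand-computed 4-point Pearson
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 4)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(agreement_stats(data.frame(p_original = x,
                                          p_updated = y))$pearson, hand)
  const <- data.frame(p_original = c(0.1, 0.1, 0.1),
                      p_updated = c(0.1, 0.2, 0.3))
  expect_error(agreement_stats(const), "constant")
})

test_that("comparison regression recovers kinked relationships exactly", {
  x <- seq(1, 60, by = 1) / 100
  kink <- function(px) 0.6 * pmin(100 * px, 30) +
    0.8 * pmax(100 * px - 30, 0)
  pairs <- data.frame(p_original = x, p_updated = kink(x) / 100)
  fit <- fit_comparison_regression(pairs, knot = 30)
  expect_equal(unname(fit$segment_slopes), c(0.6, 0.8), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-6)
  # identity line: slope 1, intercept 0 in both segments
  ident <- data.frame(p_original = x, p_updated = x)
  fid <- fit_comparison_regression(ident, knot = 30)
  expect_equal(unname(fid$segment_slopes), c(1, 1), tolerance = 1e-8)
  # all points below the knot: single segment, flagged
  low <- data.frame(p_original = x[x < 0.25], p_updated = x[x < 0.25])
  expect_warning(flow <- fit_comparison_regression(low, knot = 30),
                 "single segment")
  expect_true(attr(flow, "single_segment"))
})

test_that("median read-off and tolerance intervals behave at fixed points", {
  x <- seq(0.01, 0.4, length.out = 101)
  self <- data.frame(p_original = x, p_updated = x)
  mt <- median_tolerance(self)
  expect_equal(mt$median_original, 100 * median(x))
  expect_equal(mt$point_updated, mt$median_original, tolerance = 1e-9)
  expect_equal(mt$ti_upper - mt$ti_lower, 0, tolerance = 1e-9)
  expect_equal(percent_reduction(mt$median_original, mt$point_updated), 0,
               tolerance = 1e-9)

  # constant offset of one percentage point, noise-free
  off <- data.frame(p_original = x, p_updated = x - 0.01)
  mo <- median_tolerance(off)
  expect_equal(mo$point_updated, mo$median_original - 1, tolerance = 1e-9)
  expect_equal(mo$ti_upper - mo$ti_lower, 0, tolerance = 1e-8)

  # nearest-scenario convention and normal-theory TI also run
  mn <- median_tolerance(off, method = "nearest", ti = "normal")
  expect_equal(mn$point_updated, mn$median_original - 1, tolerance = 0.3)
  expect_lte(mn$ti_lower, mn$point_updated)
  expect_gte(mn$ti_upper, mn$point_updated)

  expect_error(median_tolerance(off[1:5, ]), "20")
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("empirical tolerance intervals achieve near-nominal coverage", {
  # heteroscedastic linear truth; check conditional coverage at the median
  reps <- 200
  n <- 300
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    x <- runif(n, 1, 50)
    sd_x <- 0.3 + 0.02 * x
    y <- 0.7 * x + rnorm(n, 0, sd_x)
    pairs <- data.frame(p_original = x / 100, p_updated = y / 100)
    mt <- median_tolerance(pairs)
    # true 95% conditional band at the median of x
    mu <- 0.7 * mt$median_original
    s <- 0.3 + 0.02 * mt$median_original
    lo_true <- mu + qnorm(0.025) * s
    hi_true <- mu + qnorm(0.975) * s
    # a draw from the true conditional law falls inside the TI
    ynew <- rnorm(1, mu, s)
    covered[r] <- ynew >= mt$ti_lower && ynew <= mt$ti_upper
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("percent reduction reproduces tabulated arithmetic", {
  expect_equal(round(percent_reduction(2.5, 1.4)), 44)
  expect_equal(percent_reduction(10.4, 4.8), 100 * (10.4 - 4.8) / 10.4)
  expect_equal(round(percent_reduction(10.4, 4.8), 1), 53.8)
})

test_that("full comparison report is coherent across cells", {
  model <- fixture_model()
  cmp <- compare_models(model, scale_incidence(model, 0.55),
                        ages = c(60, 80), sexes = "female")
  t <- cmp$table
  expect_equal(nrow(t), 4)  # 2 outcomes x 2 ages
  expect_true(all(abs(t$pearson) <= 1))
  expect_true(all(t$spearman >= 0.9999))
  expect_true(all(t$ti_lower <= t$point_updated + 1e-9))
  expect_true(all(t$point_updated <= t$ti_upper + 1e-9))
  expect_true(all(t$pct_reduction > 0))
  expect_output(print(cmp), "tolerance")
})
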