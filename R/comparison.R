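#' Exhaustive clinical-scenario grid
#'
#' All combinations of the six binary clinical risk factors and a ladder of
#' BMD T-scores, per age and sex, at a fixed BMI of 25 kg/m^2: with the
#' default eight T-scores (0 to -3.5 SD in 0.5 SD steps) this gives
#' 2^6 x 8 = 512 scenarios per age/sex. This is an array of all possible
#' combinations, not a population sample.
#'
#' @param ages ages in years (default 50, 60, 70, 80).
#' @param sexes sexes to include.
#' @param tscores T-score ladder.
#' @param bmi fixed BMI.
#' @param crf_names names of the binary risk factors spanned by the grid.
#' @return data.frame in the [predict.frax_model()] profile layout plus
#'   `scenario_id` and `crf_bitmask`, lexicographically ordered and
#'   duplicate-free.
#' @export
build_scenario_grid <- function(ages = c(50, 60, 70, 80),
                                sexes = SEXES,
                                tscores = seq(0, -3.5, by = -0.5),
                                bmi = 25, crf_names = CRF_NAMES) {
  stop_if_not(length(ages) > 0, "ages must be non-empty")
  bits <- expand.grid(rep(list(0:1), length(crf_names)),
                      KEEP.OUT.ATTRS = FALSE)
  names(bits) <- crf_names
  bitmask <- as.vector(as.matrix(bits) %*% 2^(seq_along(crf_names) - 1))
  cell <- expand.grid(tscore_i = seq_along(tscores),
                      comb = seq_len(nrow(bits)),
                      KEEP.OUT.ATTRS = FALSE)
  frame <- expand.grid(cell_i = seq_len(nrow(cell)), sex = sexes,
                       age = ages, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  out <- data.frame(age = frame$age, sex = frame$sex, bmi = bmi,
                    tscore = tscores[cell$tscore_i[frame$cell_i]])
  out[crf_names] <- bits[cell$comb[frame$cell_i], ]
  out$crf_bitmask <- bitmask[cell$comb[frame$cell_i]]
  out$scenario_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Paired 10-year probabilities under two models
#'
#' @param model_a,model_b [calibrate()]d models (a = original/surrogate,
#'   b = updated/authentic).
#' @param grid a [build_scenario_grid()].
#' @param outcome `"hip"` or `"mof"`.
#' @return `grid` with columns `outcome`, `p_original`, `p_updated`
#'   (proportions).
#' @export
pair_probabilities <- function(model_a, model_b, grid,
                               outcome = c("hip", "mof")) {
  outcome <- match.arg(outcome)
  grid$outcome <- outcome
  grid$p_original <- predict(model_a, grid, outcome)
  grid$p_updated <- predict(model_b, grid, outcome)
  grid
}

#' Agreement correlations between paired probabilities
#'
#' @param pairs a [pair_probabilities()] result (or any data.frame with
#'   `p_original`, `p_updated`).
#' @return list with `pearson` and `spearman` correlation coefficients.
#' @export
agreement_stats <- function(pairs) {
  x <- pairs$p_original
  y <- pairs$p_updated
  stop_if_not(length(x) >= 3, "need at least 3 pairs")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for a constant probability vector")
  list(pearson = cor(x, y), spearman = cor(x, y, method = "spearman"))
}

#' Segmented regression of updated on original probabilities
#'
#' Fits a continuous two-segment least-squares line of the updated model's
#' probability on the original model's probability, in percent units with a
#' knot at 30 percentage points (the probability relationship follows
#' different linear trends below and above that level). Falls back to a
#' single line, with a warning, when a segment holds fewer than two points.
#'
#' @param pairs a [pair_probabilities()] result.
#' @param knot breakpoint in percentage points.
#' @return a [segmented_fit()] in percent units, with attribute
#'   `"single_segment"` set when the fallback was taken.
#' @export
fit_comparison_regression <- function(pairs, knot = 30) {
  x <- 100 * pairs$p_original
  y <- 100 * pairs$p_updated
  single <- sum(x < knot) < 2 || sum(x > knot) < 2
  if (single) {
    warning("fewer than 2 points on one side of the knot; ",
            "fitting a single segment")
    fit <- segmented_fit(x, y, knots = numeric(0))
  } else {
    fit <- suppressWarnings(segmented_fit(x, y, knots = knot))
    single <- length(fit$knots) == 0L
  }
  attr(fit, "single_segment") <- single
  fit
}

#' Updated-model probability at the original model's median, with a 95% TI
#'
#' Reads the comparison at the 50th percentile of the original
#' (surrogate) model's probability distribution: the point estimate is the
#' segmented-regression prediction at the median (or the paired value of
#' the scenario nearest the median with `method = "nearest"`), and the 95%
#' tolerance interval is formed from the regression residuals — their
#' empirical 2.5th/97.5th percentiles added to the point estimate by
#' default, or a normal-theory k-factor interval with `ti = "normal"`.
#'
#' @param pairs a [pair_probabilities()] result (>= 20 pairs).
#' @param fit optional precomputed [fit_comparison_regression()].
#' @param method point-estimate convention at the median.
#' @param ti tolerance-interval construction.
#' @return list with `median_original`, `point_updated`, `ti_lower`,
#'   `ti_upper` (all in percent).
#' @export
median_tolerance <- function(pairs, fit = NULL,
                             method = c("regression", "nearest"),
                             ti = c("empirical", "normal")) {
  method <- match.arg(method)
  ti <- match.arg(ti)
  stop_if_not(nrow(pairs) >= 20,
              "need at least 20 pairs for a tolerance interval")
  if (is.null(fit)) fit <- fit_comparison_regression(pairs)
  x <- 100 * pairs$p_original
  med <- unname(median(x))
  point <- if (method == "regression") predict(fit, med) else
    100 * pairs$p_updated[which.min(abs(x - med))]
  r <- residuals(fit)
  if (ti == "empirical") {
    q <- unname(quantile(r, c(0.025, 0.975), type = 7))
    lo <- point + q[1]
    hi <- point + q[2]
  } else {
    n <- length(r)
    k <- qnorm(0.975) * sqrt((n - 1) / qchisq(0.05, n - 1)) * sqrt(1 + 1 / n)
    s <- sqrt(sum(r^2) / (n - 1))
    lo <- point - k * s
    hi <- point + k * s
  }
  list(median_original = med, point_updated = unname(point),
       ti_lower = unname(lo), ti_upper = unname(hi))
}

#' Percent reduction at the median
#'
#' @param median_original,point_updated probabilities in percent, e.g. from
#'   [median_tolerance()]; the median must be positive.
#' @return `100 * (original - updated) / original`.
#' @export
percent_reduction <- function(median_original, point_updated) {
  stop_if_not(median_original > 0, "median probability must be positive")
  100 * (median_original - point_updated) / median_original
}

#' Compare two calibrated models over clinical-scenario grids
#'
#' Runs the full agreement analysis for each (age, sex, outcome) cell:
#' paired probabilities over the 512-scenario grid, Pearson and Spearman
#' correlations, the 30%-knot segmented regression, the median of the
#' original model's distribution with the updated model's point estimate
#' and 95% tolerance interval, and the percent reduction at the median.
#'
#' @param model_a,model_b [calibrate()]d models (original and updated).
#' @param ages,sexes,outcomes cells to evaluate.
#' @param knot comparison-regression breakpoint in percentage points.
#' @param ti tolerance-interval construction, see [median_tolerance()].
#' @return object of class `frax_comparison`: `table` (one row per cell,
#'   percent units) and `pairs` (all paired probabilities).
#' @export
compare_models <- function(model_a, model_b,
                           ages = c(50, 60, 70, 80), sexes = SEXES,
                           outcomes = c("mof", "hip"), knot = 30,
                           ti = "empirical") {
  grid <- build_scenario_grid(ages, sexes)
  all_pairs <- list()
  rows <- list()
  for (out in outcomes) {
    pairs <- pair_probabilities(model_a, model_b, grid, out)
    all_pairs[[out]] <- pairs
    for (s in sexes) for (a in ages) {
      cell <- pairs[pairs$age == a & pairs$sex == s, ]
      st <- agreement_stats(cell)
      fit <- suppressWarnings(fit_comparison_regression(cell, knot))
      mt <- median_tolerance(cell, fit, ti = ti)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = out, sex = s, age = a,
        pearson = st$pearson, spearman = st$spearman,
        median_original = mt$median_original,
        point_updated = mt$point_updated,
        ti_lower = mt$ti_lower, ti_upper = mt$ti_upper,
        pct_reduction = percent_reduction(mt$median_original,
                                          mt$point_updated),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 pairs = do.call(rbind, all_pairs),
                 knot = knot),
            class = "frax_comparison")
}

#' @export
print.frax_comparison <- function(x, ...) {
  cat("10-year probability (%) at the median of the original model's",
      "distribution,\nwith 95% tolerance intervals for the updated model\n\n")
  t <- x$table
  for (out in unique(t$outcome)) {
    cat(toupper(out), "\n")
    for (s in unique(t$sex)) {
      d <- t[t$outcome == out & t$sex == s, ]
      cat(" ", s, "\n")
      cat(sprintf("    age %2d  original %5.1f  update %5.1f (%4.1f-%4.1f)  r %.3f\n",
                  d$age, d$median_original, d$point_updated,
                  d$ti_lower, d$ti_upper, d$pearson), sep = "")
    }
  }
  invisible(x)
}

#' @export
summary.frax_comparison <- function(object, ...) {
  t <- object$table
  structure(list(table = t,
                 r_range = range(t$pearson),
                 reduction_range = range(t$pct_reduction)),
            class = "summary.frax_comparison")
}

#' @export
print.summary.frax_comparison <- function(x, ...) {
  cat(sprintf("Correlation (Pearson) across cells: %.4f to %.4f\n",
              x$r_range[1], x$r_range[2]))
  cat(sprintf("Reduction at the median: %.1f%% to %.1f%%\n",
              x$reduction_range[1], x$reduction_range[2]))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Scatter of updated versus original probabilities with identity line
#'
#' @param x a `frax_comparison`.
#' @param outcome which outcome to draw.
#' @param ... passed to [plot()].
#' @export
plot.frax_comparison <- function(x, outcome = "hip", ...) {
  p <- x$pairs[x$pairs$outcome == outcome, ]
  graphics::plot(100 * p$p_original, 100 * p$p_updated,
                 xlab = "Original model 10-year probability (%)",
                 ylab = "Updated model 10-year probability (%)",
                 pch = 16, cex = 0.4, col = "grey30", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
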