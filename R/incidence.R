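#' Regional population weights
#'
#' Default weights for the three macro-regions covered by the sentinel
#' cities — Southeast 42%, Northeast 28%, South 14% of the national
#' population — renormalised to sum to one over the covered regions.
#'
#' @return named numeric vector of weights summing to 1.
#' @export
default_region_weights <- function() {
  w <- c(Southeast = 0.42, Northeast = 0.28, South = 0.14)
  w / sum(w)
}

#' Combine city incidence into a region-weighted national rate table
#'
#' Converts each city's counts to rates per 100,000 person-years and forms,
#' per sex and age band, the convex combination of city rates weighted by
#' the population share of the city's region (weights are renormalised over
#' the regions present).
#'
#' @param samples city registry data as returned by
#'   [generate_city_incidence()].
#' @param weights named numeric vector, region -> weight; must cover every
#'   region present, each region must contribute exactly one city.
#' @return rate table data.frame (`sex`, `age_lo`, `age_hi`, `rate`), rate
#'   per 100,000 person-years.
#' @export
combine_regions <- function(samples, weights = default_region_weights()) {
  regions <- unique(samples$region)
  stop_if_not(all(regions %in% names(weights)),
              "every region in the data needs a weight")
  per_region_cities <- tapply(samples$city, samples$region,
                              function(x) length(unique(x)))
  stop_if_not(all(per_region_cities == 1L),
              "each region must be represented by exactly one city")
  w <- weights[regions]
  stop_if_not(sum(w) > 0, "region weights sum to zero")
  w <- w / sum(w)
  key <- interaction(samples$sex, samples$age_lo, drop = TRUE)
  bands_per_city <- table(samples$city)
  stop_if_not(length(unique(bands_per_city)) == 1L &&
                all(table(key) == length(regions)),
              "age bands do not match across cities")
  samples$rate <- samples$count / samples$person_years * 1e5
  samples$w <- unname(w[samples$region])
  agg <- aggregate(cbind(wrate = rate * w) ~ sex + age_lo + age_hi,
                   data = samples, FUN = sum)
  names(agg)[names(agg) == "wrate"] <- "rate"
  agg <- agg[order(agg$sex, agg$age_lo), ]
  rownames(agg) <- NULL
  agg
}

#' Default incidence-regression breakpoints
#'
#' Knots at 62 and 87 years for men and 62 and 82 years for women.
#'
#' @return named list of numeric knot vectors.
#' @export
default_breakpoints <- function() {
  list(male = c(62, 87), female = c(62, 82))
}

#' Piecewise log-linear regression of incidence on age
#'
#' Smooths an age-band rate table by fitting, per sex, a continuous
#' piecewise-linear model of log incidence on band midpoint age with fixed
#' breakpoints (see [segmented_fit()] for the truncated-basis machinery
#' guaranteeing continuity). Band midpoints are 52.5, 57.5, ..., with 92.5
#' for the open 90+ band.
#'
#' @param table rate table (`sex`, `age_lo`, `age_hi`, `rate` per 100,000).
#' @param breakpoints named list of knots per sex; see
#'   [default_breakpoints()].
#' @param zero_policy how to treat zero-rate bands before taking logs:
#'   `"exclude"` drops them, `"add-half"` replaces the count-free rate with
#'   half the smallest positive rate in the sex's table.
#' @param count_weights optional vector of per-row least-squares weights
#'   (e.g. observed counts), aligned with `table` rows.
#' @return named list (one [segmented_fit()] per sex), class
#'   `piecewise_incidence`.
#' @export
fit_piecewise_loglinear <- function(table,
                                    breakpoints = default_breakpoints(),
                                    zero_policy = c("exclude", "add-half"),
                                    count_weights = NULL) {
  zero_policy <- match.arg(zero_policy)
  fits <- lapply(intersect(SEXES, unique(table$sex)), function(s) {
    d <- table[table$sex == s, ]
    w <- if (is.null(count_weights)) NULL else count_weights[table$sex == s]
    if (any(d$rate <= 0)) {
      if (zero_policy == "exclude") {
        keep <- d$rate > 0
        w <- w[keep]
        d <- d[keep, ]
      } else {
        d$rate[d$rate <= 0] <- min(d$rate[d$rate > 0]) / 2
      }
    }
    stop_if_not(nrow(d) > 0, "no positive rates to fit")
    mid <- band_midpoint(d$age_lo, d$age_hi)
    segmented_fit(mid, d$rate, knots = breakpoints[[s]], weights = w,
                  log_y = TRUE)
  })
  structure(setNames(fits, intersect(SEXES, unique(table$sex))),
            class = "piecewise_incidence")
}

#' @export
print.piecewise_incidence <- function(x, ...) {
  for (s in names(x)) {
    cat(s, "incidence fit:\n")
    print(x[[s]])
  }
  invisible(x)
}

#' Predict a smoothed incidence rate at an age
#'
#' @param fit a [fit_piecewise_loglinear()] result (or a single
#'   [segmented_fit()]).
#' @param age ages in years; must lie in \[50, 110\].
#' @param sex `"male"` or `"female"`; required when `fit` holds both sexes.
#' @return rate per 100,000 person-years; continuous in age.
#' @export
predict_rate <- function(fit, age, sex = NULL) {
  stop_if_not(all(age >= 50 & age <= 110), "age must be in [50, 110]")
  if (inherits(fit, "piecewise_incidence")) {
    stop_if_not(!is.null(sex), "sex is required for a two-sex fit")
    fit <- fit[[match.arg(sex, SEXES)]]
  }
  predict(fit, age)
}

#' Evaluate a smoothed fit on the standard age bands
#'
#' @param fit a [fit_piecewise_loglinear()] result.
#' @return rate table (`sex`, `age_lo`, `age_hi`, `rate`) at band midpoints.
#' @export
smoothed_rate_table <- function(fit) {
  bands <- age_bands()
  do.call(rbind, lapply(names(fit), function(s) {
    data.frame(sex = s, age_lo = bands$age_lo, age_hi = bands$age_hi,
               rate = predict_rate(fit, bands$midpoint, s),
               stringsAsFactors = FALSE)
  }))
}

#' National annual fracture burden
#'
#' Expected annual number of fractures from age 50, per sex:
#' \eqn{\sum_{bands} rate/10^5 \times population}. Also constructible
#' directly from known per-sex counts via `national_burden()`.
#'
#' @param rates a rate table (`sex`, `age_lo`, `age_hi`, `rate`) or a
#'   [fit_piecewise_loglinear()] result (evaluated at band midpoints).
#' @param demography data.frame (`sex`, `age_lo`, `age_hi`, `population`)
#'   covering every band in the rate table.
#' @return object of class `national_burden`: list with `men`, `women`,
#'   `total` and `male_share` (proportion).
#' @export
estimate_national_counts <- function(rates, demography) {
  if (inherits(rates, "piecewise_incidence")) rates <- smoothed_rate_table(rates)
  m <- merge(rates, demography[c("sex", "age_lo", "age_hi", "population")],
             by = c("sex", "age_lo", "age_hi"))
  stop_if_not(nrow(m) == nrow(rates),
              "demography is missing bands present in the rate table")
  counts <- tapply(m$rate / 1e5 * m$population, m$sex, sum)
  pick <- function(s) if (is.na(counts[s])) 0 else unname(counts[s])
  national_burden(men = pick("male"), women = pick("female"))
}

#' @rdname estimate_national_counts
#' @param men,women expected annual fracture counts per sex.
#' @export
national_burden <- function(men, women) {
  stop_if_not(men >= 0 && women >= 0, "counts must be non-negative")
  structure(list(men = men, women = women, total = men + women,
                 male_share = men / (men + women)),
            class = "national_burden")
}

#' @export
print.national_burden <- function(x, ...) {
  cat(sprintf(
    "Estimated annual fractures: %s, of which %s (%.0f%%) in men and %s in women\n",
    format(round(x$total), big.mark = ","),
    format(round(x$men), big.mark = ","), 100 * x$male_share,
    format(round(x$women), big.mark = ",")))
  invisible(x)
}

#' Impute non-hip major osteoporotic fracture rates from hip rates
#'
#' Applies age- and sex-specific site-to-hip incidence ratios (the Swedish
#' ratio method used when site-specific national incidence is unavailable)
#' to a hip rate table: site rate = hip rate x site ratio. The combined
#' `mof` row treats the four sites as a single first-event hazard, i.e. hip
#' rate x (1 + sum of site ratios).
#'
#' @param hip rate table (`sex`, `age_lo`, `age_hi`, `rate`).
#' @param ratios ratio table from [generate_ratio_table()] (both sexes may
#'   be row-bound); must cover every band/sex in `hip`.
#' @return rate table with an additional `site` column covering `hip`, the
#'   three non-hip sites, and the combined `mof`.
#' @export
impute_mof_rates <- function(hip, ratios) {
  out <- do.call(rbind, lapply(seq_len(nrow(hip)), function(i) {
    r <- ratios[ratios$sex == hip$sex[i] & ratios$age_lo == hip$age_lo[i], ]
    stop_if_not(nrow(r) == length(MOF_SITES) &&
                  all(MOF_SITES %in% r$site),
                sprintf("missing site ratios for %s band [%s, %s)",
                        hip$sex[i], hip$age_lo[i], hip$age_hi[i]))
    site_rates <- setNames(r$ratio, r$site)[MOF_SITES] * hip$rate[i]
    data.frame(sex = hip$sex[i], age_lo = hip$age_lo[i],
               age_hi = hip$age_hi[i],
               site = c("hip", MOF_SITES, "mof"),
               rate = c(hip$rate[i], unname(site_rates),
                        hip$rate[i] + sum(site_rates)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
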