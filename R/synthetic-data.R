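#' Ground-truth hip-fracture incidence surface
#'
#' Defines the true age- and sex-specific hip-fracture incidence
#' \eqn{\lambda(a, s)} (per 100,000 person-years) used by the synthetic
#' registry generator, as a continuous piecewise log-linear curve per sex.
#' Defaults emulate the epidemiology the pipeline is designed for: incidence
#' rising exponentially with age, with knots at 62 and 87 years in men and
#' 62 and 82 years in women, and a female excess of about 50% from age 70
#' onwards, produced by a steeper female rise through the fifties and
#' sixties followed by near-parallel log-linear segments.
#'
#' @param male,female lists with elements `log_rate_50` (log rate per
#'   100,000 at age 50), `knots` (increasing ages) and `slopes` (one per
#'   segment, log-rate per year of age; length `length(knots) + 1`).
#' @return an object of class `ground_truth_incidence`; its
#'   `female_excess_factor_70plus` element records the realised
#'   female-to-male rate ratio at age 75.
#' @seealso [true_rate()], [generate_city_incidence()]
#' @export
ground_truth_incidence <- function(
    male = list(log_rate_50 = log(20), knots = c(62, 87),
                slopes = c(0.055, 0.092, 0.050)),
    female = list(log_rate_50 = log(18), knots = c(62, 82),
                  slopes = c(0.098, 0.092, 0.060))) {
  for (s in list(male, female)) {
    stop_if_not(length(s$slopes) == length(s$knots) + 1L,
                "need one slope per segment (length(knots) + 1)")
    stop_if_not(!is.unsorted(s$knots, strictly = TRUE),
                "knots must be strictly increasing")
  }
  obj <- structure(list(male = male, female = female),
                   class = "ground_truth_incidence")
  obj$female_excess_factor_70plus <-
    true_rate(obj, 75, "female") / true_rate(obj, 75, "male")
  obj
}

#' Evaluate a ground-truth incidence curve
#'
#' @param truth a [ground_truth_incidence()] object.
#' @param age numeric vector of ages (years, >= 50).
#' @param sex `"male"` or `"female"`.
#' @return incidence rate per 100,000 person-years at each age.
#' @export
true_rate <- function(truth, age, sex) {
  s <- truth[[match.arg(sex, SEXES)]]
  bounds <- c(50, s$knots, Inf)
  logr <- rep(s$log_rate_50, length(age))
  for (j in seq_along(s$slopes)) {
    run <- pmax(0, pmin(age, bounds[j + 1]) - bounds[j])
    logr <- logr + s$slopes[j] * run
  }
  exp(logr)
}

#' Default city panel for the synthetic registry
#'
#' Three sentinel cities, one per covered macro-region, with
#' age-standardised rates lowest in Belem, intermediate in Vitoria and
#' highest in Joinville (scale factors multiply the ground-truth rates).
#'
#' @return data.frame with columns `city`, `region`, `scale`.
#' @export
default_cities <- function() {
  data.frame(city   = c("Belem", "Vitoria", "Joinville"),
             region = c("Northeast", "Southeast", "South"),
             scale  = c(0.8, 1.0, 1.2),
             stringsAsFactors = FALSE)
}

#' Simulate city-level hip-fracture registry counts
#'
#' Draws Poisson fracture counts per city, sex and 5-year age band with mean
#' `scale * lambda(midpoint, sex) * person_years / 1e5`, where `lambda` is
#' the ground-truth incidence.
#'
#' @param truth a [ground_truth_incidence()] object.
#' @param cities data.frame with columns `city`, `region`, `scale`
#'   (positive multipliers); see [default_cities()].
#' @param person_years_per_band positive scalar (or vector recycled over
#'   bands) of person-years of observation per city/sex/band.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return data.frame (`city`, `region`, `sex`, `age_lo`, `age_hi`,
#'   `count`, `person_years`), bands jointly covering ages 50+.
#' @export
generate_city_incidence <- function(truth, cities = default_cities(),
                                    person_years_per_band = 30000,
                                    seed = 1L) {
  stop_if_not(all(person_years_per_band > 0),
              "person_years_per_band must be positive")
  stop_if_not(all(cities$scale > 0), "city scale factors must be positive")
  bands <- age_bands()
  grid <- expand.grid(band = seq_len(nrow(bands)), sex = SEXES,
                      city_i = seq_len(nrow(cities)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  py <- rep_len(person_years_per_band, nrow(bands))[grid$band]
  lambda <- vapply(seq_len(nrow(grid)), function(i) {
    true_rate(truth, bands$midpoint[grid$band[i]], grid$sex[i])
  }, numeric(1))
  mu <- cities$scale[grid$city_i] * lambda * py / 1e5
  counts <- with_seed(seed, rpois(length(mu), mu))
  data.frame(city = cities$city[grid$city_i],
             region = cities$region[grid$city_i],
             sex = grid$sex,
             age_lo = bands$age_lo[grid$band],
             age_hi = bands$age_hi[grid$band],
             count = counts,
             person_years = py,
             stringsAsFactors = FALSE)
}

#' Synthetic national demography from age 50
#'
#' Deterministic population counts per sex and 5-year band, declining
#' exponentially with age, scaled so that both sexes together total
#' `total_population`, with the female share rising with age (differential
#' survival).
#'
#' @param total_population total population aged 50+ across both sexes.
#' @param decline per-year exponential decline of band population with age.
#' @return data.frame (`region`, `sex`, `age_lo`, `age_hi`, `population`).
#' @export
generate_demography <- function(total_population = 5e7, decline = 0.045) {
  bands <- age_bands()
  base <- exp(-decline * (bands$midpoint - 52.5))
  female_frac <- 0.52 + 0.004 * (bands$midpoint - 52.5)
  raw <- c(base * (1 - female_frac), base * female_frac)
  pop <- round(raw / sum(raw) * total_population)
  data.frame(region = "National",
             sex = rep(SEXES, each = nrow(bands)),
             age_lo = rep(bands$age_lo, 2),
             age_hi = rep(bands$age_hi, 2),
             population = pop,
             stringsAsFactors = FALSE)
}

#' Gompertz life table for ages 50-110
#'
#' Annual death hazard \eqn{h(a) = a_0 \exp(b (a - 50) + o_s)} with a
#' sex-specific offset \eqn{o_s} (default male excess mortality of
#' \eqn{e^{0.45} \approx 1.57}).
#'
#' @param gompertz_a positive baseline hazard at age 50 (female, offset 0).
#' @param gompertz_b non-negative log-slope per year of age.
#' @param sex_offset named numeric offsets on the log-hazard scale for
#'   `male` and `female`.
#' @return data.frame (`sex`, `age`, `hazard`) for integer ages 50-110.
#' @export
generate_life_table <- function(gompertz_a = 0.004, gompertz_b = 0.085,
                                sex_offset = c(male = 0.45, female = 0)) {
  stop_if_not(gompertz_a > 0 && gompertz_b >= 0,
              "Gompertz parameters must be positive")
  ages <- 50:110
  do.call(rbind, lapply(SEXES, function(s) {
    data.frame(sex = s, age = ages,
               hazard = gompertz_a *
                 exp(gompertz_b * (ages - 50) + unname(sex_offset[s])),
               stringsAsFactors = FALSE)
  }))
}

#' Site-to-hip incidence ratios for the other major osteoporotic fractures
#'
#' Age-band-specific ratios of clinical spine, distal forearm and proximal
#' humerus fracture incidence to hip fracture incidence, by sex. Each site
#' ratio declines log-linearly with age, so the total MOF:hip ratio
#' (1 + sum of site ratios) is strictly decreasing: forearm fractures
#' dominate in the fifties, hip fractures in the eighties.
#'
#' @param sex `"male"` or `"female"`.
#' @return data.frame (`sex`, `age_lo`, `age_hi`, `site`, `ratio`).
#' @export
generate_ratio_table <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  pars <- if (sex == "female") {
    list(spine = c(1.10, -0.020), forearm = c(3.50, -0.065),
         humerus = c(0.90, -0.025))
  } else {
    list(spine = c(1.20, -0.020), forearm = c(1.60, -0.060),
         humerus = c(0.70, -0.020))
  }
  bands <- age_bands()
  do.call(rbind, lapply(MOF_SITES, function(site) {
    p <- pars[[site]]
    data.frame(sex = sex, age_lo = bands$age_lo, age_hi = bands$age_hi,
               site = site,
               ratio = p[1] * exp(p[2] * (bands$midpoint - 52.5)),
               stringsAsFactors = FALSE)
  }))
}
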