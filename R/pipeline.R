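#' Pipeline configuration
#'
#' All knobs of the end-to-end run, JSON-serialisable without loss. The
#' defaults define the documented reference run: three sentinel cities
#' weighted 0.42/0.28/0.14 by region, default incidence breakpoints, and
#' an "updated" model calibrated to the reference incidence scaled by
#' 0.55 (emulating a revision built on roughly halved hip-fracture rates).
#'
#' @param seed master RNG seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param cities data.frame (`city`, `region`, `scale`).
#' @param person_years_per_band registry person-years per city/sex/band.
#' @param region_weights named region weights.
#' @param breakpoints named list of incidence-regression knots per sex.
#' @param zero_policy zero-rate handling in the log-rate regression.
#' @param time_step probability-engine evaluation grid.
#' @param ti_method tolerance-interval construction.
#' @param incidence_scale_updated factor applied to fracture incidence for
#'   the comparison's updated model.
#' @param total_population national population aged 50+.
#' @param comparison_ages ages evaluated in the model comparison.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cities = default_cities(),
                            person_years_per_band = 30000,
                            region_weights = default_region_weights(),
                            breakpoints = default_breakpoints(),
                            zero_policy = "exclude",
                            time_step = "annual",
                            ti_method = "empirical",
                            incidence_scale_updated = 0.55,
                            total_population = 5e7,
                            comparison_ages = c(50, 60, 70, 80)) {
  structure(list(seed = as.integer(seed), cities = cities,
                 person_years_per_band = person_years_per_band,
                 region_weights = region_weights,
                 breakpoints = breakpoints, zero_policy = zero_policy,
                 time_step = time_step, ti_method = ti_method,
                 incidence_scale_updated = incidence_scale_updated,
                 total_population = total_population,
                 comparison_ages = comparison_ages),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the reconstructed config.
#' @export
write_pipeline_config <- function(config, path) {
  config <- unclass(config)
  config$region_weights <- as.list(config$region_weights)  # keep names
  jsonlite::write_json(config, path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cities <- as.data.frame(x$cities, stringsAsFactors = FALSE)
  x$region_weights <- unlist(x$region_weights)
  do.call(pipeline_config, x)
}

#' Serialise a calibrated model to JSON
#'
#' Per-sex arrays of age and baseline hip/MOF/death hazards plus the
#' embedded risk-factor model.
#'
#' @param model a [calibrate()]d `frax_model`.
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed `frax_model` (read).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(hazards = lapply(model$hazards, as.list),
         model = unclass(model$model)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rf <- risk_factor_model(as.data.frame(x$model$crfs),
                          gradient_hip = x$model$gradient_hip,
                          gradient_mof = x$model$gradient_mof,
                          bmi_log_rr_per_unit = x$model$bmi_log_rr_per_unit,
                          tscore_mean_slope = x$model$tscore_mean_slope)
  structure(list(hazards = lapply(x$hazards, as.data.frame), model = rf),
            class = "frax_model")
}

#' Run the full model-synthesis and comparison pipeline
#'
#' Wires the stages end to end: synthetic registry generation, regional
#' combination, piecewise log-linear smoothing, national burden estimation,
#' ratio-based MOF imputation, hazard calibration of an original and an
#' (incidence-rescaled) updated model, and the scenario-grid comparison.
#' Deterministic given `config$seed`. When `outdir` is supplied, every
#' intermediate table and model is written (CSV/JSON) together with a
#' manifest of MD5 hashes.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if missing).
#' @param verbose print stage-boundary progress with row counts?
#' @return object of class `frax_pipeline`: all intermediate artifacts
#'   (`truth`, `city_samples`, `rates_raw`, `fit`, `rates_smoothed`,
#'   `burden`, `mof_rates`, `model_original`, `model_updated`,
#'   `comparison`, and `manifest` when files were written).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- ground_truth_incidence()
  samples <- generate_city_incidence(
    truth, config$cities, config$person_years_per_band,
    seed = derive_seed(config$seed, "city_incidence"))
  say("stage synth: %d registry rows", nrow(samples))
  rates_raw <- combine_regions(samples, config$region_weights)
  fit <- fit_piecewise_loglinear(rates_raw, config$breakpoints,
                                 zero_policy = config$zero_policy)
  rates_smoothed <- smoothed_rate_table(fit)
  say("stage incidence: %d combined bands", nrow(rates_smoothed))
  demography <- generate_demography(config$total_population)
  burden <- estimate_national_counts(rates_smoothed, demography)
  ratios <- rbind(generate_ratio_table("female"), generate_ratio_table("male"))
  mof_rates <- impute_mof_rates(rates_smoothed, ratios)
  life_table <- generate_life_table()
  rf_model <- generate_risk_factor_model(
    seed = derive_seed(config$seed, "risk_factor_model"))
  model_original <- calibrate(rates_smoothed, mof_rates, life_table, rf_model)
  model_updated <- scale_incidence(model_original,
                                   config$incidence_scale_updated)
  say("stage calibrate: models for %d ages", nrow(model_original$hazards$female))
  comparison <- compare_models(model_original, model_updated,
                               ages = config$comparison_ages,
                               ti = config$ti_method)
  say("stage compare: %d cells", nrow(comparison$table))
  result <- structure(
    list(config = config, truth = truth, city_samples = samples,
         rates_raw = rates_raw, fit = fit, rates_smoothed = rates_smoothed,
         demography = demography, burden = burden, mof_rates = mof_rates,
         life_table = life_table, rf_model = rf_model,
         model_original = model_original, model_updated = model_updated,
         comparison = comparison),
    class = "frax_pipeline")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(seed = config$seed)
    paths <- c(
      write_table_csv(samples, file.path(outdir, "city_incidence.csv"), meta),
      write_table_csv(rates_raw, file.path(outdir, "rates_raw.csv"), meta),
      write_table_csv(rates_smoothed,
                      file.path(outdir, "rates_smoothed.csv"), meta),
      write_table_csv(demography, file.path(outdir, "demography.csv"), meta),
      write_table_csv(mof_rates, file.path(outdir, "mof_rates.csv"), meta),
      write_table_csv(life_table, file.path(outdir, "life_table.csv"), meta),
      write_model_json(model_original,
                       file.path(outdir, "model_original.json")),
      write_model_json(model_updated, file.path(outdir, "model_updated.json")),
      write_pipeline_config(config, file.path(outdir, "config.json")))
    jsonlite::write_json(
      comparison$table, file.path(outdir, "comparison_report.json"),
      dataframe = "rows", digits = NA)
    paths <- c(paths, file.path(outdir, "comparison_report.json"))
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         dataframe = "rows")
    result$manifest <- manifest
  }
  result
}

#' @export
print.frax_pipeline <- function(x, ...) {
  cat("End-to-end fracture-probability pipeline (seed ",
      x$config$seed, ")\n\n", sep = "")
  print(x$burden)
  cat("\n")
  print(x$comparison)
  invisible(x)
}
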