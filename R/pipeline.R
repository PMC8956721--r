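# Orchestration: simulate (or read) a multi-city study, fit both exposure
# series per city, pool, compute BLUPs, impacts and comparison metrics,
# and write tidy output tables plus a run manifest.

#' Fit every city of a study for one exposure source
#'
#' @param cities List of [city_record()] objects (missingness should be
#'   aligned first for cross-source comparability).
#' @param exposure `"station"` or `"reanalysis"`.
#' @param ... Passed to [fit_city()].
#' @return List with `fits` and `assocs` (both per city).
#' @export
fit_study <- function(cities, exposure = c("station", "reanalysis"), ...) {
  exposure <- match.arg(exposure)
  res <- lapply(cities, function(ct) fit_city(ct, exposure, ...))
  list(fits = lapply(res, `[[`, "fit"),
       assocs = lapply(res, `[[`, "assoc"))
}

#' Run the full comparative pipeline
#'
#' Executes simulate (or read) -> first-stage fits for both exposure
#' sources -> meta-regression -> BLUPs -> MMT and attributable impacts
#' with Monte Carlo eCIs -> exposure comparison (agreement, qAIC, RFS),
#' and writes all result tables and a JSON run manifest to `outdir`.
#' Idempotent under a fixed seed.
#'
#' @param config A [sim_config()] (used to simulate unless `input_dir`
#'   names pre-existing city CSVs).
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param seed Master seed; defaults to `config$seed`. All Monte Carlo
#'   per-city seeds derive from it.
#' @param input_dir Optional directory with `cities.csv` metadata and one
#'   `<city>.csv` per city, as written by a previous run.
#' @param meta_formula Fixed-effect meta-predictor formula.
#' @param meta_struct Random-effect structure passed to [fit_meta()].
#' @param n_mc Monte Carlo samples for the eCIs.
#' @return Invisible list with all intermediate and final objects
#'   (`study`, `fits`, `meta`, `blups`, `impacts`, `comparison`,
#'   `tables`).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         seed = config$seed, input_dir = NULL,
                         meta_formula = ~ log(gdp_like) + mean_temp +
                           temp_iqr,
                         meta_struct = "unstr", n_mc = 1000L) {
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stages[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  run_stage <- function(name, city, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for city '%s': %s",
                   name, city, conditionMessage(e)), call. = FALSE))
  }

  if (is.null(input_dir)) {
    study <- simulate_study(config)
    cities <- study$cities
    metadata <- study$metadata
    truth <- study$truth
  } else {
    metadata <- utils::read.csv(file.path(input_dir, "cities.csv"))
    cities <- lapply(seq_len(nrow(metadata)), function(i) {
      f <- file.path(input_dir, paste0(metadata$city[i], ".csv"))
      if (!file.exists(f))
        stop("missing city file for city '", metadata$city[i], "': ", f)
      read_city_csv(f, city = metadata$city[i],
                    country = metadata$country[i], zone = metadata$zone[i],
                    gdp_like = metadata$gdp_like[i])
    })
    truth <- NULL
    study <- NULL
  }
  cities <- lapply(cities, align_city_exposures)
  tick("simulate")

  sources <- c("station", "reanalysis")
  fits <- lapply(sources, function(src)
    lapply(seq_along(cities), function(i)
      run_stage(paste0("first_stage_", src), cities[[i]]$city,
                fit_city(cities[[i]], src))))
  names(fits) <- sources
  tick("first_stage")

  meta <- lapply(sources, function(src) {
    md <- meta_dataset(lapply(fits[[src]], `[[`, "assoc"), metadata,
                       formula = meta_formula)
    fit <- fit_meta(md, struct = meta_struct)
    list(md = md, fit = fit, het = heterogeneity_stats(md))
  })
  names(meta) <- sources
  tick("meta")

  blups <- lapply(sources, function(src) compute_blups(meta[[src]]$fit))
  names(blups) <- sources
  tick("blups")

  impacts <- lapply(sources, function(src) {
    per_city <- lapply(seq_along(cities), function(i) {
      run_stage("impacts", cities[[i]]$city, {
        x <- switch(src, station = cities[[i]]$data$temp_station,
                    reanalysis = cities[[i]]$data$temp_reanalysis)
        curve <- find_mmt(blups[[src]][[i]], x)
        monte_carlo_eci(curve, cities[[i]], src, n_samples = n_mc,
                        seed = derive_seed(seed, i,
                                           5L + match(src, sources)))
      })
    })
    country <- metadata$country
    by_country <- lapply(unique(country), function(cn)
      aggregate_impacts(per_city[country == cn], "country", cn))
    global <- aggregate_impacts(per_city, "global", "Global")
    list(city = per_city, country = by_country, global = global)
  })
  names(impacts) <- sources
  tick("impacts")

  agree <- do.call(rbind, lapply(cities, function(ct)
    cbind(city = ct$city,
          agreement_metrics(ct$data$temp_station,
                            ct$data$temp_reanalysis))))
  rfs <- do.call(rbind, lapply(seq_along(cities), function(i)
    relative_fitting_score(fits$station[[i]]$fit,
                           fits$reanalysis[[i]]$fit)))
  cmp <- merge(agree, rfs, by = "city")
  cmp_country <- summarize_comparison(cmp, metadata$country)
  cmp_global <- summarize_comparison(cmp)
  tick("compare")

  tables <- list(
    cities = metadata,
    first_stage = do.call(rbind, lapply(sources, function(src)
      do.call(rbind, lapply(fits[[src]], function(f)
        data.frame(city = f$fit$city, exposure_source = src,
                   n_obs = f$fit$n_obs, dispersion = f$fit$dispersion,
                   qaic = f$fit$qaic))))),
    meta_summary = do.call(rbind, lapply(sources, function(src) {
      m <- meta[[src]]
      data.frame(exposure_source = src,
                 q_stat = m$het$Q, q_df = m$het$df, i2 = m$het$I2,
                 psi1_max_eigen = max(eigen(m$fit$Psi1)$values),
                 psi2_max_eigen = max(eigen(m$fit$Psi2)$values),
                 converged = m$fit$converged)
    })),
    blups = do.call(rbind, lapply(sources, function(src)
      do.call(rbind, lapply(blups[[src]], function(b)
        data.frame(city = b$city, exposure_source = src,
                   coef = seq_along(b$eta), value = b$eta))))),
    impacts = do.call(rbind, lapply(sources, function(src)
      impacts_table(c(impacts[[src]]$city, impacts[[src]]$country,
                      list(impacts[[src]]$global))))),
    comparison = cmp,
    comparison_summary = rbind(cmp_country, cmp_global))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(outdir,
                                               paste0(nm, ".csv")),
                       row.names = FALSE)
    if (is.null(input_dir)) {
      cdir <- file.path(outdir, "cities")
      dir.create(cdir, showWarnings = FALSE)
      for (ct in cities) write_city_csv(ct, file.path(cdir,
                                                      paste0(ct$city,
                                                             ".csv")))
      jsonlite::write_json(truth[c("city", "global")],
                           file.path(outdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(seed = seed,
                     config = unclass(config),
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("mortclim")),
                     stage_seconds = stages)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(study = study, cities = cities, metadata = metadata,
                 truth = truth, fits = fits, meta = meta, blups = blups,
                 impacts = impacts, comparison = cmp,
                 comparison_summary = rbind(cmp_country, cmp_global),
                 tables = tables, stages = stages))
}
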