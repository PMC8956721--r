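# Exposure-series agreement metrics, missingness alignment, and the
# relative fitting score (RFS) comparing the predictive ability of two
# candidate exposure series for the same mortality outcome.

#' Symmetric missingness alignment of two exposure series
#'
#' Sets each series missing wherever the other is missing, so that models
#' fitted to either are estimated on literally the same days — a
#' precondition for comparing their qAICs.
#'
#' @param station,proxy Numeric daily series on the same date index.
#' @param dates Optional common date vector (length-checked).
#' @return List with elements `station` and `proxy` sharing an identical
#'   non-missing day set.
#' @export
align_missingness <- function(station, proxy, dates = NULL) {
  if (length(station) != length(proxy))
    stop("mismatched date indices: series lengths differ")
  if (!is.null(dates) && length(dates) != length(station))
    stop("mismatched date indices: 'dates' length differs")
  miss <- is.na(station) | is.na(proxy)
  station[miss] <- NA
  proxy[miss] <- NA
  list(station = station, proxy = proxy)
}

#' Apply symmetric missingness alignment to a city record
#'
#' @param city A [city_record()].
#' @return The record with both temperature columns masked symmetrically.
#' @export
align_city_exposures <- function(city) {
  stopifnot(inherits(city, "city_record"))
  al <- align_missingness(city$data$temp_station, city$data$temp_reanalysis)
  city$data$temp_station <- al$station
  city$data$temp_reanalysis <- al$proxy
  city
}

#' Agreement metrics between two daily exposure series
#'
#' Pearson correlation, mean bias (proxy minus station, deg C) and RMSE
#' over paired non-missing days.
#'
#' @param station,proxy Numeric daily series on the same date index.
#' @return Data frame with `r`, `bias`, `rmse`, `n` and a
#'   `zero_variance` flag (correlation undefined).
#' @export
agreement_metrics <- function(station, proxy) {
  if (length(station) != length(proxy))
    stop("mismatched date indices: series lengths differ")
  ok <- !is.na(station) & !is.na(proxy)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 paired non-missing days")
  s <- station[ok]; p <- proxy[ok]
  zv <- stats::sd(s) == 0 || stats::sd(p) == 0
  if (zv) warning("zero-variance series; correlation undefined")
  data.frame(r = if (zv) NA_real_ else stats::cor(s, p),
             bias = mean(p - s),
             rmse = sqrt(mean((p - s)^2)),
             n = n, zero_variance = zv)
}

#' Relative fitting score
#'
#' `RFS = qAIC(reanalysis) - qAIC(station)`: negative values indicate a
#' superior predictive ability of the reanalysis series, positive values
#' favour the station series. Both fits must use the identical sample
#' (same rows and response), which symmetric missingness alignment
#' guarantees; this is asserted, not assumed. Near-ties
#' (`|RFS| < 1e-9`) are reported as exactly zero.
#'
#' @param fit_station,fit_reanalysis `"fs_fit"` objects for the two
#'   exposure series fitted to the same city.
#' @return Data frame with `city`, `qaic_station`, `qaic_reanalysis`,
#'   `rfs`.
#' @export
relative_fitting_score <- function(fit_station, fit_reanalysis) {
  stopifnot(inherits(fit_station, "fs_fit"),
            inherits(fit_reanalysis, "fs_fit"))
  if (fit_station$n_obs != fit_reanalysis$n_obs)
    stop("fits use different numbers of observations; align missingness first")
  if (!isTRUE(all.equal(fit_station$y, fit_reanalysis$y)))
    stop("fits use different response vectors; not comparable")
  rfs <- fit_reanalysis$qaic - fit_station$qaic
  if (abs(rfs) < 1e-9) rfs <- 0
  data.frame(city = if (is.null(fit_station$city)) NA_character_
             else fit_station$city,
             qaic_station = fit_station$qaic,
             qaic_reanalysis = fit_reanalysis$qaic,
             rfs = rfs)
}

#' Summarise comparison records by group
#'
#' @param records Data frame with at least `rfs` (e.g. rbind-ed
#'   [relative_fitting_score()] rows), optionally `r` (agreement).
#' @param group Grouping vector (e.g. country), one element per record.
#' @return Data frame per group: median RFS, counts of negative / zero /
#'   positive RFS, and median correlation when available.
#' @export
summarize_comparison <- function(records, group = rep("Global",
                                                      nrow(records))) {
  stopifnot(nrow(records) >= 1, length(group) == nrow(records))
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), group),
                               function(idx) {
    rfs <- records$rfs[idx]
    data.frame(group = as.character(group[idx[1]]),
               n = length(idx),
               median_rfs = stats::median(rfs),
               n_negative = sum(rfs < 0),
               n_zero = sum(rfs == 0),
               n_positive = sum(rfs > 0),
               median_r = if ("r" %in% names(records))
                 stats::median(records$r[idx], na.rm = TRUE) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
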