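# Synthetic multi-city generator with a known exposure-lag-response surface.
# Provides ground truth (risk curve, attributable fractions, which exposure
# series generated the deaths) against which every downstream stage of the
# two-stage pipeline can be validated.

#' Simulation configuration
#'
#' Parameters of the synthetic multi-city study. Temperatures follow a
#' seasonal cycle plus AR(1) noise; deaths are overdispersed counts whose
#' log-mean carries a lag-distributed V-shaped temperature effect anchored
#' at a known minimum mortality temperature; a degraded proxy exposure
#' (attenuated anomalies plus white noise) mimics the error structure of a
#' gridded reanalysis product relative to a station record.
#'
#' @param n_cities Number of cities.
#' @param years Years of daily data per city.
#' @param baseline_deaths Expected daily deaths at the MMT (positive).
#' @param season_amp Amplitude (deg C) of the annual temperature cycle.
#' @param ar_coef AR(1) coefficient of temperature noise, in `[0, 1)`.
#' @param temp_sd Innovation standard deviation (deg C) of the AR(1) noise.
#' @param proxy_noise_sd SD (deg C) of proxy measurement error.
#' @param proxy_attenuation Lambda in `(0, 1]` scaling proxy anomalies
#'   toward the day-of-year climatological mean.
#' @param overdispersion Variance inflation `phi >= 1` of daily counts
#'   (`Var = phi * mean`).
#' @param mmt_true True minimum mortality temperature (deg C).
#' @param heat_slope,cold_slope Cumulative log-RR per deg C beyond
#'   `mmt_true` on the hot / cold side (non-negative).
#' @param lag_decay Geometric decay rate in `(0, 1)` of the lag weights
#'   over lags 0..21 (normalised to sum to 1).
#' @param seed Integer master seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_cities = 20L, years = 5L, baseline_deaths = 30,
                       season_amp = 8, ar_coef = 0.7, temp_sd = 2,
                       proxy_noise_sd = 1.0, proxy_attenuation = 0.9,
                       overdispersion = 1.5, mmt_true = 21,
                       heat_slope = log(1.05), cold_slope = log(1.01),
                       lag_decay = 0.7, seed = 1L) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  chk(is.numeric(n_cities) && n_cities >= 1, "n_cities", "must be >= 1")
  chk(is.numeric(years) && years >= 1, "years", "must be >= 1")
  chk(baseline_deaths > 0, "baseline_deaths", "must be positive")
  chk(season_amp >= 0, "season_amp", "must be >= 0")
  chk(ar_coef >= 0 && ar_coef < 1, "ar_coef", "must be in [0, 1)")
  chk(temp_sd >= 0, "temp_sd", "must be >= 0")
  chk(proxy_noise_sd >= 0, "proxy_noise_sd", "must be >= 0")
  chk(proxy_attenuation > 0 && proxy_attenuation <= 1,
      "proxy_attenuation", "must be in (0, 1]")
  chk(overdispersion >= 1, "overdispersion", "must be >= 1")
  chk(is.finite(mmt_true), "mmt_true", "must be finite")
  chk(heat_slope >= 0, "heat_slope", "must be >= 0")
  chk(cold_slope >= 0, "cold_slope", "must be >= 0")
  chk(lag_decay > 0 && lag_decay < 1, "lag_decay", "must be in (0, 1)")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be an integer")
  structure(list(
    n_cities = as.integer(n_cities), years = as.integer(years),
    baseline_deaths = baseline_deaths, season_amp = season_amp,
    ar_coef = ar_coef, temp_sd = temp_sd,
    proxy_noise_sd = proxy_noise_sd, proxy_attenuation = proxy_attenuation,
    overdispersion = overdispersion, mmt_true = mmt_true,
    heat_slope = heat_slope, cold_slope = cold_slope,
    lag_decay = lag_decay, seed = as.integer(seed),
    maxlag = 21L), class = "sim_config")
}

# Deterministic sub-seed for city i and purpose offset; kept below 2^31.
derive_seed <- function(seed, i, offset = 0L)
  (as.integer(seed) + 7919L * as.integer(i) + 104729L * as.integer(offset)) %%
    2147483647L

# City-level climate parameters (mean temperature, seasonal phase), drawn
# deterministically from the master seed so every op can regenerate them.
city_params <- function(config, city_index) {
  set.seed(derive_seed(config$seed, city_index, 0L))
  list(mean = stats::runif(1, 10, 18),
       phase = stats::runif(1, -0.3, 0.3))
}

#' Simulate a city's daily temperature series
#'
#' `T_t = mean + season_amp * cos(2 pi doy / 365.25 + phase) + e_t` with
#' `e_t` an AR(1) process with innovation SD `temp_sd`. Real Gregorian
#' dates (leap days included) starting 1 January 2010.
#'
#' @param config A [sim_config()].
#' @param city_index City index (>= 1).
#' @param lead Extra days generated before the record start (lag burn-in).
#' @return Data frame with columns `date` and `temp`.
#' @export
simulate_temperature <- function(config, city_index, lead = 0L) {
  stopifnot(inherits(config, "sim_config"))
  cp <- city_params(config, city_index)
  start <- as.Date("2010-01-01") - lead
  end <- as.Date(sprintf("%d-12-31", 2009L + config$years))
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  seas <- cp$mean +
    config$season_amp * cos(2 * pi * doy / 365.25 + cp$phase)
  set.seed(derive_seed(config$seed, city_index, 1L))
  n <- length(dates)
  if (config$temp_sd > 0) {
    innov <- stats::rnorm(n, 0, config$temp_sd)
    e <- as.numeric(stats::filter(innov, config$ar_coef,
                                  method = "recursive"))
  } else e <- numeric(n)
  data.frame(date = dates, temp = seas + e)
}

#' Degrade an exposure series into a reanalysis-like proxy
#'
#' `proxy_t = mu_t + lambda * (T_t - mu_t) + eps_t` where `mu_t` is the
#' day-of-year climatological mean of the input, `lambda` attenuates
#' anomalies (shrinking extremes) and `eps ~ N(0, noise_sd^2)` is white
#' measurement error.
#'
#' @param temp Numeric daily series (finite).
#' @param dates Dates aligned with `temp` (for the climatological mean).
#' @param noise_sd SD of the added white noise (deg C).
#' @param attenuation Lambda in `(0, 1]`.
#' @param seed Integer seed.
#' @return Numeric proxy series of the same length.
#' @export
degrade_exposure <- function(temp, dates, noise_sd = 1, attenuation = 0.9,
                             seed = 1L) {
  if (attenuation <= 0) stop("'attenuation' must be positive")
  if (any(!is.finite(temp))) stop("'temp' must be finite")
  stopifnot(length(temp) == length(dates))
  doy <- pmin(as.integer(format(as.Date(dates), "%j")), 365L)
  mu <- stats::ave(temp, doy)
  set.seed(seed)
  mu + attenuation * (temp - mu) + stats::rnorm(length(temp), 0, noise_sd)
}

#' True risk surface of the generator
#'
#' The ground-truth overall cumulative exposure-response curve: a V shape
#' anchored at `mmt_true`, with per-lag geometric weights `w_l` over lags
#' 0..21 summing to 1 so that the lag-summed effect at constant exposure
#' equals the cumulative curve.
#'
#' @param config A [sim_config()].
#' @return Object of class `"risk_surface"`: list with `fun(x)` returning
#'   the cumulative log-RR, `mmt`, and `weights` (length 22).
#' @export
true_risk_surface <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$lag_decay^(0:config$maxlag)
  w <- w / sum(w)
  mmt <- config$mmt_true
  hs <- config$heat_slope; cs <- config$cold_slope
  fun <- function(x)
    ifelse(x >= mmt, hs * (x - mmt), cs * (mmt - x))
  structure(list(fun = fun, mmt = mmt, weights = w), class = "risk_surface")
}

#' Evaluate the true cumulative log relative risk
#'
#' @param surface A [true_risk_surface()].
#' @param x Exposure values (deg C).
#' @return Cumulative log-RR relative to the true MMT (0 at the MMT,
#'   non-negative elsewhere).
#' @export
true_cumulative_logrr <- function(surface, x) {
  stopifnot(inherits(surface, "risk_surface"), all(is.finite(x)))
  surface$fun(x)
}

#' Simulate overdispersed daily death counts
#'
#' Log mean = `log(baseline) + seasonal term + day-of-week effects +
#' sum_l w_l * f(x[t-l])` with `f` the true cumulative curve, so that at
#' constant exposure the lag-summed contribution equals
#' [true_cumulative_logrr()]. Counts are negative binomial parameterised so
#' that `Var = phi * mean` (quasi-Poisson variance law); Poisson when
#' `phi = 1`. Without lag history, the first 21 counts are `NA` (unusable).
#'
#' @param temp Daily exposure series (deg C).
#' @param dates Dates aligned with `temp`.
#' @param surface A [true_risk_surface()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param history Optional exposure values for the 21 days preceding
#'   `temp[1]` (most recent last); when supplied all counts are usable.
#' @param seasonal_amp Amplitude of the log-scale seasonal mortality cycle.
#' @param dow_effects Length-7 log-scale day-of-week effects (Mon..Sun).
#' @return Integer vector of daily deaths (leading `NA`s if no history).
#' @export
simulate_mortality <- function(temp, dates, surface, config, seed = 1L,
                               history = NULL,
                               seasonal_amp = 0.10,
                               dow_effects = c(0, -0.01, -0.02, -0.01,
                                               0, 0.02, 0.03)) {
  stopifnot(inherits(surface, "risk_surface"), inherits(config, "sim_config"),
            length(temp) == length(dates), length(dow_effects) == 7L)
  L <- config$maxlag
  if (length(temp) < L + 1L) stop("need at least 22 days of exposure")
  x <- c(history, temp)
  nh <- length(history)
  if (nh > 0 && nh < L)
    stop("'history' must supply at least 21 days when given")
  contrib <- surface$fun(x) * NA_real_
  ok <- is.finite(x)
  contrib[ok] <- surface$fun(x[ok])
  w <- surface$weights
  n <- length(temp)
  lagsum <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    idx <- nh + t - (0:L)
    if (all(idx >= 1L) && all(is.finite(contrib[idx])))
      lagsum[t] <- sum(w * contrib[idx])
  }
  doy <- as.integer(format(as.Date(dates), "%j"))
  dow <- as.integer(format(as.Date(dates), "%u"))  # 1 = Monday
  logmu <- log(config$baseline_deaths) +
    seasonal_amp * cos(2 * pi * doy / 365.25) +
    dow_effects[dow] + lagsum
  mu <- exp(logmu)
  set.seed(seed)
  y <- rep(NA_integer_, n)
  use <- is.finite(mu)
  if (config$overdispersion > 1) {
    y[use] <- stats::rnbinom(sum(use), mu = mu[use],
                             size = mu[use] / (config$overdispersion - 1))
  } else {
    y[use] <- stats::rpois(sum(use), mu[use])
  }
  y
}

# Independent day-by-day loop computing the true attributable numbers from
# the generator's own curve; deliberately scalar so it can serve as an
# oracle for the vectorised impacts module.
true_attributable <- function(deaths, temp, surface) {
  an_cold <- 0; an_heat <- 0; tot <- 0
  for (t in seq_along(deaths)) {
    d <- deaths[t]; x <- temp[t]
    if (is.na(d) || is.na(x)) next
    tot <- tot + d
    lr <- surface$fun(x)
    an <- d * (1 - exp(-lr))
    if (x < surface$mmt) an_cold <- an_cold + an
    else if (x > surface$mmt) an_heat <- an_heat + an
  }
  list(an_cold = an_cold, an_heat = an_heat, total_deaths = tot,
       af_cold = 100 * an_cold / tot, af_heat = 100 * an_heat / tot)
}

#' Simulate a complete multi-city study
#'
#' Generates per-city daily series (true/station exposure, degraded proxy
#' exposure, overdispersed deaths), city metadata (country and climate-zone
#' labels, a GDP-like covariate, mean temperature and IQR), and the ground
#' truth: the risk surface and the realised per-city and global cold/heat
#' attributable fractions computed from the true curve and true exposure.
#'
#' @param config A [sim_config()].
#' @param cities_per_country Cities grouped into synthetic countries of
#'   (at most) this size.
#' @return Object of class `"sim_study"`: list with `cities` (list of
#'   [city_record()]), `metadata` (data frame), `truth` (surface, per-city
#'   and global attributable numbers/fractions) and `config`.
#' @export
simulate_study <- function(config, cities_per_country = 4L) {
  stopifnot(inherits(config, "sim_config"))
  surface <- true_risk_surface(config)
  L <- config$maxlag
  cities <- vector("list", config$n_cities)
  truth_city <- vector("list", config$n_cities)
  meta <- vector("list", config$n_cities)
  for (i in seq_len(config$n_cities)) {
    tt <- simulate_temperature(config, i, lead = L)
    rec_idx <- seq.int(L + 1L, nrow(tt))
    temp <- tt$temp[rec_idx]
    dates <- tt$date[rec_idx]
    proxy <- degrade_exposure(temp, dates,
                              noise_sd = config$proxy_noise_sd,
                              attenuation = config$proxy_attenuation,
                              seed = derive_seed(config$seed, i, 2L))
    deaths <- simulate_mortality(temp, dates, surface, config,
                                 seed = derive_seed(config$seed, i, 3L),
                                 history = tt$temp[seq_len(L)])
    id <- sprintf("city%03d", i)
    country <- sprintf("country%02d",
                       1L + (i - 1L) %/% as.integer(cities_per_country))
    mean_temp <- mean(temp)
    zone <- if (mean_temp < 13) "cool" else
      if (mean_temp < 16) "temperate" else "warm"
    set.seed(derive_seed(config$seed, i, 4L))
    gdp_like <- exp(stats::rnorm(1, 10, 0.5))
    cities[[i]] <- city_record(
      city = id, country = country, zone = zone, gdp_like = gdp_like,
      data = data.frame(date = dates, deaths = deaths,
                        temp_station = temp, temp_reanalysis = proxy))
    truth_city[[i]] <- c(list(city = id),
                         true_attributable(deaths, temp, surface))
    meta[[i]] <- data.frame(city = id, country = country, zone = zone,
                            gdp_like = gdp_like, mean_temp = mean_temp,
                            temp_iqr = stats::IQR(temp))
  }
  tc <- do.call(rbind, lapply(truth_city, as.data.frame))
  truth <- list(
    surface = surface,
    city = tc,
    global = list(
      an_cold = sum(tc$an_cold), an_heat = sum(tc$an_heat),
      total_deaths = sum(tc$total_deaths),
      af_cold = 100 * sum(tc$an_cold) / sum(tc$total_deaths),
      af_heat = 100 * sum(tc$an_heat) / sum(tc$total_deaths)))
  structure(list(cities = cities, metadata = do.call(rbind, meta),
                 truth = truth, config = config),
            class = "sim_study")
}
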