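# Shared fixtures, all generated in code.

# Small config used across tests; slopes strong enough to detect with a
# few years of data.
test_config <- function(...) {
  sim_config(n_cities = 2L, years = 2L, baseline_deaths = 30,
             overdispersion = 1.2, seed = 123L, ...)
}

# One simulated city with full lag history (no leading NAs).
make_test_city <- function(config = test_config(), i = 1L) {
  simulate_study(config)$cities[[i]]
}

# A city built from raw vectors, bypassing simulation.
raw_city <- function(deaths, station, proxy = station,
                     start = as.Date("2015-01-01"), id = "toy") {
  n <- length(deaths)
  city_record(city = id, country = "X", zone = "Z",
              data = data.frame(date = seq(start, by = "day",
                                           length.out = n),
                                deaths = deaths, temp_station = station,
                                temp_reanalysis = proxy))
}

# Scalar meta dataset from vectors of estimates/variances.
scalar_md <- function(theta, s2, group = rep("g1", length(theta)),
                      formula = ~1) {
  assocs <- lapply(seq_along(theta), function(i)
    structure(list(eta = theta[i], vcov = matrix(s2[i], 1, 1),
                   spec = spline_spec(boundary = c(0, 1)),
                   percentiles = stats::quantile(0:1, 0:100 / 100),
                   range = c(0, 1), city = paste0("c", i),
                   exposure_choice = "station"),
              class = "reduced_assoc"))
  meta_dataset(assocs,
               data.frame(city = paste0("c", seq_along(theta)),
                          country = group, zone = "z"),
               formula = formula)
}
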