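# Readers/writers for city daily series and gridded exposure utilities.

#' City record
#'
#' One city's aligned daily series (deaths plus two candidate exposure
#' series) with metadata. Dates must be strictly increasing at daily
#' frequency; deaths must be non-negative integers where present.
#'
#' @param city City identifier.
#' @param country Country label.
#' @param zone Climate-zone label.
#' @param gdp_like GDP-like meta-predictor (country level).
#' @param data Data frame with columns `date`, `deaths`, `temp_station`,
#'   `temp_reanalysis`.
#' @return Object of class `"city_record"`; `mean_temp` and `temp_iqr`
#'   are computed from the station series.
#' @export
city_record <- function(city, country = NA_character_, zone = NA_character_,
                        gdp_like = NA_real_, data) {
  req <- c("date", "deaths", "temp_station", "temp_reanalysis")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable dates in 'data'")
  dd <- diff(as.numeric(data$date))
  if (nrow(data) > 1 && any(dd != 1))
    stop("dates must be strictly increasing at daily frequency")
  bad <- which(!is.na(data$deaths) &
                 (data$deaths < 0 | data$deaths != round(data$deaths)))
  if (length(bad))
    stop(sprintf("deaths must be non-negative integers (first offending row: %d)",
                 bad[1]))
  structure(list(city = as.character(city), country = as.character(country),
                 zone = as.character(zone), gdp_like = gdp_like,
                 mean_temp = mean(data$temp_station, na.rm = TRUE),
                 temp_iqr = stats::IQR(data$temp_station, na.rm = TRUE),
                 data = data[, req]),
            class = "city_record")
}

#' @export
print.city_record <- function(x, ...) {
  cat(sprintf("<city_record> %s (%s, %s): %d days, %s to %s\n",
              x$city, x$country, x$zone, nrow(x$data),
              min(x$data$date), max(x$data$date)))
  invisible(x)
}

#' Write / read a city daily series as CSV
#'
#' Columns `date` (ISO-8601), `deaths`, `temp_station`, `temp_reanalysis`;
#' missing values written as the literal `NA` token. The round trip is
#' lossless for finite values and missing markers.
#'
#' @param record A [city_record()].
#' @param path File path.
#' @export
write_city_csv <- function(record, path) {
  stopifnot(inherits(record, "city_record"))
  d <- record$data
  d$date <- format(d$date, "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_city_csv
#' @param city,country,zone,gdp_like Metadata attached to the record read.
#' @return `read_city_csv` returns a [city_record()].
#' @export
read_city_csv <- function(path, city = basename(path),
                          country = NA_character_, zone = NA_character_,
                          gdp_like = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("date", "deaths", "temp_station", "temp_reanalysis")
  extra <- setdiff(names(d), req)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  city_record(city = sub("\\.csv$", "", city), country = country,
              zone = zone, gdp_like = gdp_like, data = d[, req])
}

#' Gridded hourly temperature field
#'
#' In-memory container for a regular lat/lon/time cube of hourly 2-m
#' temperature, the shape in which reanalysis extracts arrive.
#'
#' @param lat,lon Regularly spaced, strictly increasing grid-cell centres.
#' @param time Strictly increasing hourly `POSIXct` timestamps (UTC).
#' @param values Array with dim `c(length(lat), length(lon), length(time))`.
#' @param units `"C"` or `"K"`; Kelvin is converted to Celsius at
#'   extraction.
#' @return Object of class `"gridded_field"`.
#' @export
gridded_field <- function(lat, lon, time, values, units = c("C", "K")) {
  units <- match.arg(units)
  reg <- function(v) length(v) < 2 ||
    isTRUE(all.equal(diff(v), rep(diff(v)[1], length(v) - 1)))
  if (!reg(lat) || !reg(lon))
    stop("lat/lon grids must be regularly spaced and increasing")
  if (length(time) > 1) {
    dt <- as.numeric(difftime(time[-1], time[-length(time)], units = "hours"))
    if (any(dt != 1)) stop("time must be strictly increasing hourly")
  }
  if (!identical(dim(values), c(length(lat), length(lon), length(time))))
    stop("'values' must have dim (lat, lon, time)")
  structure(list(lat = lat, lon = lon, time = time, values = values,
                 units = units), class = "gridded_field")
}

#' Extract the grid cell containing a point
#'
#' Returns the hourly series of the cell whose centre minimises the
#' great-circle distance to the point; ties break deterministically to the
#' lower linear index (latitude-major ordering). Kelvin fields are
#' converted to Celsius.
#'
#' @param field A [gridded_field()].
#' @param lat,lon Point coordinates (degrees).
#' @return Data frame with columns `time` and `temp`.
#' @export
extract_nearest_cell <- function(field, lat, lon) {
  stopifnot(inherits(field, "gridded_field"))
  hlat <- if (length(field$lat) > 1) diff(field$lat)[1] / 2 else Inf
  hlon <- if (length(field$lon) > 1) diff(field$lon)[1] / 2 else Inf
  if (lat < min(field$lat) - hlat || lat > max(field$lat) + hlat ||
      lon < min(field$lon) - hlon || lon > max(field$lon) + hlon)
    stop(sprintf(
      "point (%.3f, %.3f) outside grid bounds; nearest edge at lat [%g, %g], lon [%g, %g]",
      lat, lon, min(field$lat), max(field$lat), min(field$lon),
      max(field$lon)))
  cells <- cbind(lon = rep(field$lon, each = length(field$lat)),
                 lat = rep(field$lat, times = length(field$lon)))
  d <- geosphere::distHaversine(cells, c(lon, lat))
  idx <- which.min(round(d, 3))  # mm precision; tie-break: lower index
  i_lat <- (idx - 1L) %% length(field$lat) + 1L
  i_lon <- (idx - 1L) %/% length(field$lat) + 1L
  temp <- field$values[i_lat, i_lon, ]
  if (field$units == "K") temp <- temp - 273.15
  data.frame(time = field$time, temp = temp)
}

#' Aggregate an hourly series to local-time daily means
#'
#' Shifts timestamps by a fixed UTC offset, groups by local calendar day,
#' and averages the 24 hourly values; partial days (fewer than 24 hours)
#' are dropped with a message.
#'
#' @param hourly Data frame with columns `time` (`POSIXct`) and `temp`.
#' @param timezone_offset Offset from UTC in hours.
#' @return Data frame with columns `date` and `temp` (daily 24-h means).
#' @export
hourly_to_daily <- function(hourly, timezone_offset = 0) {
  stopifnot(all(c("time", "temp") %in% names(hourly)))
  local <- hourly$time + timezone_offset * 3600
  day <- as.Date(local, tz = "UTC")
  counts <- table(day)
  full <- names(counts)[counts == 24L]
  dropped <- sum(counts != 24L)
  if (dropped > 0)
    message(sprintf("dropping %d partial day(s) with fewer than 24 hours",
                    dropped))
  keep <- day %in% as.Date(full)
  agg <- tapply(hourly$temp[keep], droplevels(factor(day[keep])), mean)
  data.frame(date = as.Date(names(agg)), temp = as.numeric(agg))
}
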