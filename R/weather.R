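# Stochastic daily weather generation, DSSAT-style WTH file exchange, and
# thermal time.

#' Describe a site for the stochastic weather generator
#'
#' The generator targets growing-season statistics: mean temperature, mean
#' solar radiation and total rainfall over a 300-day season. `diurnal_range`
#' and `wet_day_freq` shape the daily series but are not season targets.
#'
#' @param name Site label.
#' @param latitude,longitude Decimal degrees.
#' @param altitude Metres above sea level.
#' @param season_mean_temp Growing-season mean temperature, degrees C.
#' @param season_mean_srad Growing-season mean solar radiation, MJ m-2 day-1.
#' @param season_rainfall Growing-season total rainfall, mm.
#' @param diurnal_range Mean tmax - tmin, degrees C.
#' @param wet_day_freq Stationary probability of a wet day.
#' @return Object of class `site_profile`.
#' @export
site_profile <- function(name, latitude, longitude, altitude,
                         season_mean_temp, season_mean_srad, season_rainfall,
                         diurnal_range = 10, wet_day_freq = 0.45) {
  stopifnot(season_mean_srad > 0, diurnal_range > 0,
            wet_day_freq >= 0, wet_day_freq <= 1, season_rainfall >= 0)
  structure(list(name = name, latitude = latitude, longitude = longitude,
                 altitude = altitude, season_mean_temp = season_mean_temp,
                 season_mean_srad = season_mean_srad,
                 season_rainfall = season_rainfall,
                 diurnal_range = diurnal_range,
                 wet_day_freq = wet_day_freq),
            class = "site_profile")
}

#' The two packaged contrasting study environments
#'
#' A cool highland site (1750 masl: 18 C, 16 MJ m-2 day-1, 890 mm per
#' season) and a warm lowland site (20 masl: 28 C, 17 MJ m-2 day-1,
#' 1130 mm per season), both in the equatorial cassava belt.
#'
#' @return Named list of two [site_profile()]s: `cool` and `warm`.
#' @export
default_sites <- function() {
  list(
    cool = site_profile("cool_highland", 2.4278, -76.6208, 1750,
                        season_mean_temp = 18, season_mean_srad = 16,
                        season_rainfall = 890, diurnal_range = 12,
                        wet_day_freq = 0.50),
    warm = site_profile("warm_lowland", 8.8397, -75.8019, 20,
                        season_mean_temp = 28, season_mean_srad = 17,
                        season_rainfall = 1130, diurnal_range = 10,
                        wet_day_freq = 0.40)
  )
}

SEASON_DAYS <- 300L       # planting to harvest, ~10 months
DEFAULT_PLANTING_DOY <- 115L

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature is the site mean plus a weak tropical seasonal
#' cycle and AR(1) noise; tmax/tmin are placed symmetrically around it at
#' the (noisy) diurnal range. Rain occurrence follows a two-state Markov
#' chain with the profile's stationary wet-day frequency; wet-day amounts
#' are gamma distributed with mean chosen so the expected 300-day season
#' total equals the profile target. Solar radiation is AR(1) noise around a
#' mean adjusted for cloud reduction on wet days.
#'
#' @param profile A [site_profile()].
#' @param n_years Number of calendar years (>= 1).
#' @param seed Integer seed; the series is reproducible and the caller's RNG
#'   state is untouched.
#' @param start_year First calendar year (default 2001).
#' @return A `weather_series`: data frame with columns `date`, `tmax`,
#'   `tmin`, `srad`, `rain` and the profile in attribute `site`.
#' @export
generate_weather <- function(profile, n_years, seed = 1L, start_year = 2001L) {
  stopifnot(inherits(profile, "site_profile"), n_years >= 1)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  with_seed(seed, {
    # temperature: weak annual cycle (tropics) + AR(1)
    seas <- 0.5 * sin(2 * pi * (doy - 105) / 365.25)
    tnoise <- as.numeric(stats::filter(rnorm(nd, 0, 1.2 * sqrt(1 - 0.7^2)),
                                       0.7, method = "recursive"))
    tmean <- profile$season_mean_temp + seas + tnoise
    rng <- profile$diurnal_range * runif(nd, 0.8, 1.2)
    tmax <- tmean + rng / 2
    tmin <- tmean - rng / 2
    # rain: two-state Markov occurrence, gamma amounts
    pi_w <- profile$wet_day_freq
    rho <- 0.35                              # wet-spell persistence
    p11 <- rho + (1 - rho) * pi_w
    p01 <- (1 - rho) * pi_w
    wet <- logical(nd)
    u <- runif(nd)
    wet[1] <- u[1] < pi_w
    for (i in 2:nd) wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
    rain <- numeric(nd)
    if (pi_w > 0 && any(wet)) {
      mean_amt <- profile$season_rainfall / (SEASON_DAYS * pi_w)
      shape <- 0.9
      rain[wet] <- rgamma(sum(wet), shape = shape, scale = mean_amt / shape)
    }
    # radiation: compensate the wet-day cloud factor so the mean stays on
    # target, then add AR(1) noise
    cloud <- ifelse(wet, 0.85, 1)
    sbase <- profile$season_mean_srad / (1 - 0.15 * pi_w)
    snoise <- as.numeric(stats::filter(rnorm(nd, 0, 2 * sqrt(1 - 0.5^2)),
                                       0.5, method = "recursive"))
    srad <- pmax(0.5, sbase * cloud + snoise)
  })
  records <- data.frame(date = dates, tmax = round(tmax, 1),
                        tmin = round(tmin, 1), srad = round(srad, 1),
                        rain = round(rain, 1))
  new_weather_series(records, profile)
}

#' Construct a weather series from daily records
#'
#' Validates contiguous daily dates, `tmax >= tmin`, and non-negative rain
#' and radiation.
#'
#' @param records Data frame with columns `date` (Date), `tmax`, `tmin`,
#'   `srad`, `rain`.
#' @param site Optional [site_profile()] attached as an attribute.
#' @return A `weather_series` (data frame subclass).
#' @export
weather_series <- function(records, site = NULL) {
  new_weather_series(records, site)
}

new_weather_series <- function(records, site) {
  validate_weather_records(records)
  structure(records, site = site,
            class = c("weather_series", "data.frame"))
}

validate_weather_records <- function(records) {
  if (nrow(records) == 0) stop("weather series has no records")
  need <- c("date", "tmax", "tmin", "srad", "rain")
  if (!all(need %in% names(records)))
    stop("weather records need columns: ", paste(need, collapse = ", "))
  dd <- diff(as.integer(records$date))
  if (length(dd) && any(dd != 1)) {
    stop("weather dates are not contiguous daily (first gap at row ",
         which(dd != 1)[1] + 1, ")")
  }
  bad <- which(records$tmax < records$tmin)
  if (length(bad)) stop("tmax < tmin at row ", bad[1])
  bad <- which(records$rain < 0)
  if (length(bad)) stop("negative rain at row ", bad[1])
  bad <- which(records$srad < 0)
  if (length(bad)) stop("negative srad at row ", bad[1])
  invisible(records)
}

#' Growing-season statistics of a weather series
#'
#' For every calendar year whose planting window (planting day-of-year plus
#' `season_days`) is fully covered, returns the season mean temperature,
#' mean solar radiation and total rainfall.
#'
#' @param series A `weather_series`.
#' @param planting_doy Planting day of year (default 115, late April).
#' @param season_days Season length in days (default 300).
#' @return Data frame with one row per complete season.
#' @export
season_stats <- function(series, planting_doy = DEFAULT_PLANTING_DOY,
                         season_days = SEASON_DAYS) {
  years <- unique(as.integer(format(series$date, "%Y")))
  out <- lapply(years, function(y) {
    start <- as.Date(sprintf("%d-01-01", y)) + (planting_doy - 1)
    idx <- which(series$date >= start & series$date < start + season_days)
    if (length(idx) < season_days) return(NULL)
    s <- series[idx, ]
    data.frame(year = y, mean_temp = mean((s$tmax + s$tmin) / 2),
               mean_srad = mean(s$srad), rainfall = sum(s$rain))
  })
  do.call(rbind, out)
}

#' Daily thermal time above a base temperature
#'
#' `max(0, (tmax + tmin)/2 - tbase)`, the daily-mean-minus-base form with no
#' upper optimum (vectorised).
#'
#' @param tmax,tmin Daily extremes, degrees C (`tmax >= tmin`).
#' @param tbase Base temperature, degrees C.
#' @return Thermal time in degree-days (Cd), >= 0.
#' @export
thermal_time <- function(tmax, tmin, tbase) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  pmax(0, (tmax + tmin) / 2 - tbase)
}

# ---------------------------------------------------------------------------
# File exchange: DSSAT-style .wth fixed-width text, or CSV by extension.

#' Read / write weather series files
#'
#' `.wth` files follow the DSSAT layout (site header line, `@ INSI ...`
#' station line, then `@DATE SRAD TMAX TMIN RAIN` daily rows with YYYYDDD
#' dates); any other extension is treated as CSV with columns
#' `date,tmax,tmin,srad,rain`. `write_wth()` followed by `read_wth()` is the
#' identity on records to written precision.
#'
#' @param path File path (`.wth` or `.csv`).
#' @param series A `weather_series`.
#' @return `read_wth()` returns a `weather_series`; `write_wth()` returns
#'   `path` invisibly.
#' @export
read_wth <- function(path) {
  if (grepl("\\.wth$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    hdr <- grep("^@DATE", lines)
    if (length(hdr) != 1) stop("malformed WTH file: no @DATE header in ", path)
    sta <- grep("^@ *INSI", lines)
    site <- NULL
    if (length(sta) == 1 && sta < hdr && length(lines) > sta) {
      f <- strsplit(trimws(lines[sta + 1]), "[[:space:]]+")[[1]]
      if (length(f) >= 4) {
        site <- site_profile(f[1], as.numeric(f[2]), as.numeric(f[3]),
                             as.numeric(f[4]), season_mean_temp = NA,
                             season_mean_srad = 1, season_rainfall = 0)
      }
    }
    body <- lines[(hdr + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) stop("WTH file has no daily records: ", path)
    df <- read.table(text = body, col.names = c("date7", "srad", "tmax",
                                                "tmin", "rain"))
    yr <- df$date7 %/% 1000
    dy <- df$date7 %% 1000
    records <- data.frame(
      date = as.Date(sprintf("%04d-01-01", yr)) + (dy - 1),
      tmax = df$tmax, tmin = df$tmin, srad = df$srad, rain = df$rain)
  } else {
    records <- read.csv(path, stringsAsFactors = FALSE)
    records$date <- as.Date(records$date)
    site <- NULL
  }
  new_weather_series(records, site)
}

#' @rdname read_wth
#' @export
write_wth <- function(series, path) {
  validate_weather_records(series)
  if (grepl("\\.wth$", path, ignore.case = TRUE)) {
    site <- attr(series, "site")
    name <- if (is.null(site)) "SITE" else site$name
    lat <- if (is.null(site)) 0 else site$latitude
    lon <- if (is.null(site)) 0 else site$longitude
    elev <- if (is.null(site)) 0 else site$altitude
    date7 <- as.integer(format(series$date, "%Y")) * 1000L +
      as.integer(format(series$date, "%j"))
    lines <- c(
      sprintf("*WEATHER DATA : %s", name),
      "",
      "@ INSI      LAT     LONG  ELEV",
      sprintf("  %-6s %8.4f %8.4f %5.0f", substr(gsub("[^A-Za-z0-9]", "",
                                                      name), 1, 4), lat, lon,
              elev),
      "@DATE  SRAD  TMAX  TMIN  RAIN",
      sprintf("%7d %5.1f %5.1f %5.1f %5.1f", date7, series$srad,
              series$tmax, series$tmin, series$rain))
    writeLines(lines, path)
  } else {
    df <- as.data.frame(series)[, c("date", "tmax", "tmin", "srad", "rain")]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
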