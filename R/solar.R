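# Solar geometry: NOAA low-accuracy solar position and sunrise/sunset.
# Accuracy is about +/- 1-2 minutes at the study latitudes, which is ample for
# night screening and for anchoring the sunset + 3 h reference scan.

# Fractional year (radians) at a UTC instant.
.solar_gamma <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  2 * pi / 365 * (lt$yday + (lt$hour - 12) / 24 + lt$min / 1440)
}

# Equation of time (minutes) and solar declination (radians).
.solar_eqtime <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
            - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

.solar_decl <- function(g) {
  (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
   - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
   - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
}

#' Solar elevation angle
#'
#' @param time POSIXct UTC instant(s).
#' @param lat,lon Location in decimal degrees.
#' @return Elevation of the sun above the horizon, degrees (unrefracted).
#' @export
solar_elevation <- function(time, lat, lon) {
  g <- .solar_gamma(time)
  eqtime <- .solar_eqtime(g)
  decl <- .solar_decl(g)
  lt <- as.POSIXlt(time, tz = "UTC")
  tst <- (lt$hour * 60 + lt$min + lt$sec / 60 + eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * DEG2RAD
  phi <- lat * DEG2RAD
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  90 - acos(pmin(pmax(cosz, -1), 1)) * RAD2DEG
}

#' Night test
#'
#' A time is night when the solar elevation at the location is below
#' -0.833 degrees, the standard refraction-corrected sunrise/sunset horizon.
#'
#' @inheritParams solar_elevation
#' @return Logical vector.
#' @export
is_night <- function(time, lat, lon) {
  solar_elevation(time, lat, lon) < -0.833
}

# Sunrise and sunset (UTC POSIXct) whose event falls on local calendar
# date `date` at a station with civil offset `utc_offset` hours.
.sun_event <- function(date, lat, lon, utc_offset, rise) {
  date <- as.Date(date)
  # anchor eqtime/declination at local solar noon of that date
  noon_utc <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") -
    utc_offset * 3600
  g <- .solar_gamma(noon_utc)
  eqtime <- .solar_eqtime(g)
  decl <- .solar_decl(g)
  phi <- lat * DEG2RAD
  cosha <- (cos(90.833 * DEG2RAD) / (cos(phi) * cos(decl))
            - tan(phi) * tan(decl))
  if (any(abs(cosha) > 1)) {
    stop("polar day/night: no sunrise/sunset at this latitude and date",
         call. = FALSE)
  }
  ha <- acos(cosha) * RAD2DEG
  sgn <- if (rise) 1 else -1
  minutes <- 720 - 4 * (lon + sgn * ha) - eqtime
  # minutes are past UTC midnight of the local date; shift so the *local*
  # event lands on the requested local calendar date
  utc0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  t <- utc0 + minutes * 60
  local_date <- as.Date(t + utc_offset * 3600, tz = "UTC")
  t - round(as.numeric(local_date - date)) * 86400
}

#' Sunset and sunrise bracketing one night
#'
#' Returns the UTC instants of sunset on the local calendar date `night_date`
#' and of sunrise the following local morning. Nights are keyed by the local
#' date of their sunset.
#'
#' @param night_date Local calendar date of sunset (`Date` or string).
#' @param station A [station_config()].
#' @return List with POSIXct `sunset` and `sunrise`, `sunset < sunrise`.
#' @export
night_bounds <- function(night_date, station) {
  night_date <- as.Date(night_date)
  ss <- .sun_event(night_date, station$lat, station$lon, station$utc_offset,
                   rise = FALSE)
  sr <- .sun_event(night_date + 1, station$lat, station$lon,
                   station$utc_offset, rise = TRUE)
  stopifnot(all(ss < sr))
  list(sunset = ss, sunrise = sr)
}

#' Label nocturnal scans with their night
#'
#' Maps each nocturnal UTC timestamp to the local calendar date of the most
#' recent sunset, so every scan between one sunset and the next sunrise shares
#' a night key.
#'
#' @param time POSIXct UTC instant(s); must be nocturnal.
#' @param station A [station_config()].
#' @return `Date` vector of night keys.
#' @export
assign_night <- function(time, station) {
  out <- rep(as.Date(NA), length(time))
  local_date <- as.Date(time + station$utc_offset * 3600, tz = "UTC")
  for (cand_off in c(0L, -1L, 1L)) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    d <- local_date[todo] + cand_off
    for (dd in unique(d)) {
      nb <- night_bounds(as.Date(dd, origin = "1970-01-01"), station)
      sel <- todo[d == dd]
      hit <- time[sel] >= nb$sunset & time[sel] < nb$sunrise
      out[sel[hit]] <- as.Date(dd, origin = "1970-01-01")
    }
  }
  if (anyNA(out)) {
    stop("daytime timestamp(s) cannot be assigned to a night: ",
         fmt_utc(time[which(is.na(out))[1]]), call. = FALSE)
  }
  out
}
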