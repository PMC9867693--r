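#' Local sunrise time from the NOAA solar-position approximation
#'
#' Computes local sunrise (seconds after local midnight) for a date and
#' position using the NOAA general solar-position equations (Fourier series in
#' the fractional year for declination and the equation of time, zenith
#' 90.833 degrees for refraction and solar radius).  Stated accuracy is within
#' about two minutes at low and mid latitudes, which is ample for a four-hour
#' acceptance window.
#'
#' @param date `Date` vector (local calendar date).
#' @param lat,lon Decimal degrees; vectors recycled against `date`.
#' @param utc_offset_hours Local clock offset from UTC in hours (e.g. 8 for
#'   Taiwan, which observes no daylight saving).
#' @return Numeric vector of seconds after local midnight (`NA` where the sun
#'   does not rise).
#' @examples
#' sunrise_noaa(as.Date("2015-05-01"), lat = 23.5, lon = 121, utc_offset_hours = 8)
#' @export
sunrise_noaa <- function(date, lat, lon, utc_offset_hours = 8) {
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)

  doy <- as.integer(strftime(date, "%j"))
  ndays <- ifelse(as.integer(strftime(date, "%Y")) %% 4 == 0, 366, 365)
  g <- 2 * pi / ndays * (doy - 1 + (12 - 12) / 24) # fractional year at noon

  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  latr <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- cos(zen) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
  ha <- ifelse(abs(cos_ha) <= 1, acos(cos_ha) * 180 / pi, NA_real_)

  sunrise_utc_min <- 720 - 4 * (lon + ha) - eqtime
  (sunrise_utc_min + utc_offset_hours * 60) * 60
}
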