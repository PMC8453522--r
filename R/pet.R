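#' Extraterrestrial solar radiation for a month
#'
#' Daily extraterrestrial radiation at the top of the atmosphere, evaluated at
#' the mid-month day (the 15th) with the standard FAO-56 solar geometry
#' (inverse relative Earth-Sun distance, solar declination and sunset hour
#' angle).
#'
#' @param latitude Latitude in decimal degrees; polar latitudes
#'   (|latitude| > 66.5) are not supported because the sunset hour angle is
#'   undefined under polar day/night.
#' @param month Calendar month, 1-12. Vectorised over `month`.
#' @return Radiation in MJ m-2 day-1.
#' @examples
#' extraterrestrial_radiation(48, 1:12)
#' @export
extraterrestrial_radiation <- function(latitude, month) {
  assert_number(latitude, "latitude")
  if (abs(latitude) > 66.5)
    stopf("unsupported latitude %.1f: polar day/night not handled", latitude)
  if (any(!month %in% 1:12)) stopf("month must be in 1..12")
  gsc <- 0.0820 # solar constant, MJ m-2 min-1
  cum <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))
  j <- cum[month] + 15 # mid-month day of year
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Hargreaves potential evapotranspiration
#'
#' Monthly PET from temperature and extraterrestrial radiation only:
#' `PET_day = 0.0023 * (Ra / lambda) * (tmean + 17.8) * sqrt(tmax - tmin)`,
#' clamped at zero and multiplied by the number of days in the month. The
#' latent heat of vaporisation `lambda = 2.45` MJ/kg converts radiation to its
#' evaporation-equivalent depth in mm.
#'
#' @param tmin,tmax,tmean Monthly minimum, maximum and mean air temperature
#'   (degrees C). Vectors are recycled against `year`/`month`.
#' @param latitude Site latitude, decimal degrees.
#' @param year,month Calendar year and month of each value.
#' @return PET in mm/month.
#' @examples
#' hargreaves_pet(5, 20, 12, 48, 2003, 6)
#' @export
hargreaves_pet <- function(tmin, tmax, tmean, latitude, year, month) {
  if (any(tmin > tmax)) stopf("tmin > tmax in input climate")
  ra <- extraterrestrial_radiation(latitude, month)
  pet_day <- 0.0023 * (ra / 2.45) * (tmean + 17.8) * sqrt(tmax - tmin)
  pet_day <- pmax(pet_day, 0)
  pet_day * days_in_month(year, month)
}

#' Monthly climatic water balance
#'
#' Precipitation minus Hargreaves PET for every month of a climate series.
#'
#' @param climate A data frame with columns `year`, `month`, `tmin`, `tmean`,
#'   `tmax`, `prcp` (mm) and either a `latitude` column or a `latitude`
#'   attribute; an optional `site` column is carried through.
#' @return The input data frame with columns `pet` (mm) and `wb`
#'   (P - PET, mm; may be negative) appended.
#' @export
water_balance <- function(climate) {
  lat <- climate$latitude[1] %||% attr(climate, "latitude")
  if (is.null(lat)) stopf("climate must carry a latitude column or attribute")
  climate$pet <- hargreaves_pet(climate$tmin, climate$tmax, climate$tmean,
                                lat, climate$year, climate$month)
  climate$wb <- climate$prcp - climate$pet
  climate
}
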