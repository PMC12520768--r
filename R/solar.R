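#' Sunrise and sunset times from solar geometry
#'
#' Computes civil sunrise and sunset (sun centre at 90.833 degrees zenith,
#' i.e. including standard atmospheric refraction) for a date and position,
#' using the NOAA solar-position equations. Nocturnal flight scheduling in
#' the synthetic generator, flight truncation and actogram cross-checks all
#' rely on these times; accuracy is well within +/- 5 minutes of reference
#' calculators at the latitudes handled here.
#'
#' @param lat latitude in degrees north; must lie in \[-66, 66\] (no polar
#'   day/night handling).
#' @param lon longitude in degrees east, in \[-180, 180\].
#' @param date a `Date` (or anything coercible); the civil date, UTC.
#'
#' All three arguments are recycled to a common length.
#'
#' @return A `data.frame` with `POSIXct` (UTC) columns `sunrise` and
#'   `sunset`, one row per input.
#' @examples
#' sun_events(55.98, 12.33, as.Date("2014-08-01"))
#' @export
sun_events <- function(lat, lon, date) {
  date <- as.Date(date)
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(as.numeric(lat), n)
  lon <- rep_len(as.numeric(lon), n)
  date <- rep_len(date, n)
  if (anyNA(lat) || anyNA(lon) || anyNA(date))
    stop("sun_events(): missing values in lat/lon/date", call. = FALSE)
  if (any(abs(lat) > 66))
    stop("sun_events(): |latitude| > 66 not supported (polar day/night)",
         call. = FALSE)
  if (any(abs(lon) > 180))
    stop("sun_events(): longitude outside [-180, 180]", call. = FALSE)

  rad <- pi / 180
  # Julian centuries at approximate local solar noon
  jd <- as.numeric(date) + 2440587.5 + 0.5 - lon / 360
  jc <- (jd - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(rad * gma) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * rad * gma) * (0.019993 - 0.000101 * jc) +
    sin(3 * rad * gma) * 0.000289
  omega <- 125.04 - 1934.136 * jc
  lambda <- gml + ctr - 0.00569 - 0.00478 * sin(rad * omega)
  e0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- e0 + 0.00256 * cos(rad * omega)
  decl <- asin(sin(rad * eps) * sin(rad * lambda)) / rad

  y <- tan(rad * eps / 2)^2
  eqtime <- 4 / rad * (y * sin(2 * rad * gml) - 2 * ecc * sin(rad * gma) +
    4 * ecc * y * sin(rad * gma) * cos(2 * rad * gml) -
    0.5 * y^2 * sin(4 * rad * gml) - 1.25 * ecc^2 * sin(2 * rad * gma))

  cos_ha <- cos(rad * 90.833) / (cos(rad * lat) * cos(rad * decl)) -
    tan(rad * lat) * tan(rad * decl)
  if (any(abs(cos_ha) > 1))
    stop("sun_events(): sun does not rise or set at this position/date",
         call. = FALSE)
  ha <- acos(cos_ha) / rad

  noon_min <- 720 - 4 * lon - eqtime
  base <- as.POSIXct(as.numeric(date) * 86400, origin = "1970-01-01", tz = "UTC")
  data.frame(
    sunrise = base + (noon_min - 4 * ha) * 60,
    sunset  = base + (noon_min + 4 * ha) * 60
  )
}
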