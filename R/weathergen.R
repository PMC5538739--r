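#' Climate parameters for the stochastic daily weather generator
#'
#' Defines the statistical envelope of a temperate, maritime-influenced arable
#' region: a sinusoidal seasonal temperature cycle with AR(1) daily anomalies,
#' a two-state Markov chain for precipitation occurrence with exponentially
#' distributed wet-day amounts, and a clear-sky seasonal radiation curve
#' attenuated on wet (cloudy) days.
#'
#' The defaults are calibrated to a loess hill region of Southwest Germany:
#' long-run mean annual temperature close to 9.5 degC (within the regional
#' 9-10 degC envelope) and mean annual precipitation close to 780 mm (within
#' 730-830 mm). The stationary wet-day probability of the Markov chain is
#' `p_wet_dry / (1 + p_wet_dry - p_wet_wet)`; annual precipitation is 365
#' times that probability times `precip_wet_mean`.
#'
#' @param temp_mean long-run mean annual temperature, degC.
#' @param temp_amplitude half-range of the seasonal temperature sinusoid, degC.
#' @param temp_peak_doy day of year at which the seasonal mean peaks.
#' @param temp_noise_sd standard deviation of daily temperature anomaly
#'   innovations, degC.
#' @param temp_ar1 lag-1 autocorrelation of temperature anomalies, in `[0, 1)`.
#' @param diurnal_range mean daily range `tmax - tmin`, degC.
#' @param p_wet_dry probability a dry day is followed by a wet day.
#' @param p_wet_wet probability a wet day is followed by a wet day.
#' @param precip_wet_mean mean precipitation on a wet day, mm.
#' @param rad_mean annual mean clear-sky global radiation, MJ m-2 day-1.
#' @param rad_amplitude half-range of the seasonal radiation sinusoid.
#' @param rad_peak_doy day of year of peak clear-sky radiation.
#' @param cloud_atten multiplicative attenuation of radiation on wet days,
#'   in `[0, 1]`.
#' @return an object of class `climate_params`.
#' @seealso [generate_weather()], [climate_shift()]
#' @export
#' @examples
#' p <- climate_params()
#' w <- generate_weather(p, n_years = 2, seed = 1)
#' head(w)
climate_params <- function(temp_mean = 9.5,
                           temp_amplitude = 8.8,
                           temp_peak_doy = 200,
                           temp_noise_sd = 2.4,
                           temp_ar1 = 0.72,
                           diurnal_range = 8,
                           p_wet_dry = 0.33,
                           p_wet_wet = 0.55,
                           precip_wet_mean = 5.05,
                           rad_mean = 12.5,
                           rad_amplitude = 9.5,
                           rad_peak_doy = 172,
                           cloud_atten = 0.45) {
  p <- list(
    temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    temp_peak_doy = temp_peak_doy, temp_noise_sd = temp_noise_sd,
    temp_ar1 = temp_ar1, diurnal_range = diurnal_range,
    p_wet_dry = p_wet_dry, p_wet_wet = p_wet_wet,
    precip_wet_mean = precip_wet_mean,
    rad_mean = rad_mean, rad_amplitude = rad_amplitude,
    rad_peak_doy = rad_peak_doy, cloud_atten = cloud_atten
  )
  validate_climate_params(p)
  structure(p, class = "climate_params")
}

validate_climate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(p)) {
    if (!num1(p[[f]])) stop_invalid("climate_params: field '", f, "' must be a finite number")
  }
  if (p$temp_amplitude < 0 || p$temp_noise_sd < 0 || p$diurnal_range < 0 ||
      p$precip_wet_mean < 0 || p$rad_mean < 0 || p$rad_amplitude < 0) {
    stop_invalid("climate_params: scales must be >= 0")
  }
  for (f in c("p_wet_dry", "p_wet_wet", "cloud_atten")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop_invalid("climate_params: '", f, "' must lie in [0, 1]")
  }
  if (p$temp_ar1 < 0 || p$temp_ar1 >= 1) {
    stop_invalid("climate_params: 'temp_ar1' must lie in [0, 1)")
  }
  invisible(p)
}

#' @export
print.climate_params <- function(x, ...) {
  cat("<climate_params>\n")
  cat(sprintf("  mean annual temperature : %.2f degC (amplitude %.1f)\n",
              x$temp_mean, x$temp_amplitude))
  pw <- x$p_wet_dry / (1 + x$p_wet_dry - x$p_wet_wet)
  cat(sprintf("  expected annual precip  : %.0f mm (wet-day prob %.2f)\n",
              365 * pw * x$precip_wet_mean, pw))
  invisible(x)
}

# Seasonal mean temperature on a 365-day year.
seasonal_temp <- function(p, doy) {
  p$temp_mean + p$temp_amplitude * cos(2 * pi * (doy - p$temp_peak_doy) / 365)
}

seasonal_radiation <- function(p, doy) {
  pmax(0.1, p$rad_mean + p$rad_amplitude * cos(2 * pi * (doy - p$rad_peak_doy) / 365))
}

#' Generate a synthetic multi-year daily weather series
#'
#' Produces whole 365-day calendar years of daily weather. Temperature is the
#' seasonal sinusoid plus an AR(1) anomaly; precipitation occurrence follows a
#' two-state Markov chain with exponential wet-day amounts; radiation is the
#' clear-sky seasonal curve, attenuated by `cloud_atten` on wet days. The
#' series is fully determined by `(params, n_years, seed)`.
#'
#' @param params a [climate_params()] object.
#' @param n_years number of whole years to generate (>= 1).
#' @param seed integer RNG seed; the caller's RNG state is left untouched.
#' @param station_label label stored on the result.
#' @return a `weather_series`: a data frame with columns
#'   `year, doy, tmin, tmean, tmax, precip, radiation` and attributes
#'   `station_label` and `seed`. `tmin <= tmean <= tmax` on every day.
#' @export
generate_weather <- function(params, n_years, seed, station_label = "synthetic") {
  stopifnot(inherits(params, "climate_params"))
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years < 1) {
    stop_invalid("generate_weather: n_years must be >= 1")
  }
  n_years <- as.integer(n_years)
  n <- n_years * 365L
  doy <- rep(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L)

  out <- with_seed(seed, {
    # AR(1) temperature anomalies around the seasonal curve
    innov <- stats::rnorm(n, 0, params$temp_noise_sd)
    anom <- numeric(n)
    if (n > 0) anom[1] <- innov[1]
    phi <- params$temp_ar1
    if (n > 1) for (i in 2:n) anom[i] <- phi * anom[i - 1] + innov[i]
    tmean <- seasonal_temp(params, doy) + anom

    # diurnal half-range, jittered but never negative
    half <- pmax(0, params$diurnal_range / 2 +
                   stats::rnorm(n, 0, params$diurnal_range / 8))
    tmin <- tmean - half
    tmax <- tmean + half

    # two-state Markov occurrence, exponential amounts
    u <- stats::runif(n)
    wet <- logical(n)
    if (n > 0) {
      pw <- params$p_wet_dry / (1 + params$p_wet_dry - params$p_wet_wet)
      wet[1] <- u[1] < pw
      if (n > 1) for (i in 2:n) {
        wet[i] <- u[i] < (if (wet[i - 1]) params$p_wet_wet else params$p_wet_dry)
      }
    }
    precip <- numeric(n)
    nwet <- sum(wet)
    if (nwet > 0 && params$precip_wet_mean > 0) {
      precip[wet] <- stats::rexp(nwet, rate = 1 / params$precip_wet_mean)
    }

    radiation <- seasonal_radiation(params, doy)
    radiation[wet] <- radiation[wet] * params$cloud_atten

    data.frame(year = year, doy = doy, tmin = tmin, tmean = tmean,
               tmax = tmax, precip = precip, radiation = radiation)
  })
  structure(out,
            class = c("weather_series", "data.frame"),
            station_label = station_label,
            seed = as.integer(seed))
}

#' Shift a climate envelope for scenario experiments
#'
#' Returns a copy of `params` with the long-run mean temperature shifted by
#' `delta_temp` degC and the wet-day precipitation mean scaled by
#' `precip_factor`, leaving all other parameters (and the input object)
#' unchanged. Useful for what-if comparisons of future climatic conditions
#' against a historical baseline under paired seeds.
#'
#' @param params a [climate_params()] object.
#' @param delta_temp additive temperature shift, degC.
#' @param precip_factor multiplicative factor (> 0) on wet-day mean rainfall.
#' @return a new `climate_params` object.
#' @export
climate_shift <- function(params, delta_temp = 0, precip_factor = 1) {
  stopifnot(inherits(params, "climate_params"))
  if (!is.numeric(precip_factor) || length(precip_factor) != 1L || precip_factor <= 0) {
    stop_invalid("climate_shift: precip_factor must be > 0")
  }
  out <- unclass(params)
  out$temp_mean <- out$temp_mean + delta_temp
  out$precip_wet_mean <- out$precip_wet_mean * precip_factor
  do.call(climate_params, out)
}

#' Write / read a daily weather series as CSV
#'
#' Plain comma-separated file with header
#' `year,doy,tmin,tmean,tmax,precip,radiation`; the round trip is lossless to
#' well beyond 6 decimals.
#'
#' @param series a `weather_series`.
#' @param path file path.
#' @return `write_weather` returns `path` invisibly; `read_weather` returns a
#'   `weather_series`.
#' @export
write_weather <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  df <- as.data.frame(series)
  num <- c("tmin", "tmean", "tmax", "precip", "radiation")
  for (cn in num) df[[cn]] <- sprintf("%.9f", df[[cn]])
  write_csv_strict(df, path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  df <- read_csv_strict(path)
  need <- c("year", "doy", "tmin", "tmean", "tmax", "precip", "radiation")
  if (!all(need %in% names(df))) {
    stop_invalid("read_weather: missing columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  structure(df[need], class = c("weather_series", "data.frame"),
            station_label = "file", seed = NA_integer_)
}
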