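#' Define a site climatology for the weather generator
#'
#' Parameters of the stochastic daily weather generator: a seasonal
#' temperature sinusoid (minimum in mid-January) with stationary AR(1)
#' noise, a seasonal clear-sky radiation sinusoid scaled by a daily
#' cloudiness draw, and rainfall from a two-state (wet/dry) Markov
#' chain with gamma-distributed wet-day amounts. Defaults approximate
#' the long-term climatology of Harpenden, UK (about 51.8 N).
#'
#' @param annual_mean_temp annual mean temperature, deg C.
#' @param seasonal_amplitude half-range of the seasonal cycle, deg C.
#' @param ar1_rho lag-1 autocorrelation of daily temperature anomalies,
#'   |rho| < 1.
#' @param temp_noise_sd stationary standard deviation of the anomalies,
#'   deg C.
#' @param diurnal_half_range half of the daily tmax - tmin range, deg C.
#' @param radiation_mean annual mean clear-sky-scale radiation,
#'   MJ m-2 d-1.
#' @param radiation_amplitude seasonal half-range of radiation,
#'   MJ m-2 d-1.
#' @param rain_p_wet_wet,rain_p_wet_dry Markov transition probabilities
#'   P(wet | wet) and P(wet | dry).
#' @param rain_gamma_shape,rain_gamma_mean shape and mean (mm) of
#'   wet-day rainfall amounts.
#' @param latitude degrees north.
#' @return A `climatology` object (named list).
#' @export
climatology <- function(annual_mean_temp = 9.8, seasonal_amplitude = 6.5,
                        ar1_rho = 0.7, temp_noise_sd = 2.0,
                        diurnal_half_range = 4.0,
                        radiation_mean = 10, radiation_amplitude = 8,
                        rain_p_wet_wet = 0.6, rain_p_wet_dry = 0.3,
                        rain_gamma_shape = 0.8, rain_gamma_mean = 4,
                        latitude = 51.8) {
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1", call. = FALSE)
  if (temp_noise_sd < 0 || seasonal_amplitude < 0) {
    stop("sd and amplitude must be >= 0", call. = FALSE)
  }
  probs <- c(rain_p_wet_wet, rain_p_wet_dry)
  if (any(probs < 0 | probs > 1)) {
    stop("rain transition probabilities must be in [0, 1]", call. = FALSE)
  }
  if (latitude < -90 || latitude > 90) {
    stop("latitude must be in [-90, 90]", call. = FALSE)
  }
  structure(list(annual_mean_temp = annual_mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_rho = ar1_rho, temp_noise_sd = temp_noise_sd,
                 diurnal_half_range = diurnal_half_range,
                 radiation_mean = radiation_mean,
                 radiation_amplitude = radiation_amplitude,
                 rain_p_wet_wet = rain_p_wet_wet,
                 rain_p_wet_dry = rain_p_wet_dry,
                 rain_gamma_shape = rain_gamma_shape,
                 rain_gamma_mean = rain_gamma_mean,
                 latitude = latitude),
            class = "climatology")
}

# run expr with a local, seeded RNG stream, restoring global state after
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic daily weather series
#'
#' Seed-deterministic daily weather with the statistical structure of a
#' temperate maritime site: mean temperature is a seasonal sinusoid
#' (minimum mid-January) plus stationary AR(1) noise, with tmin/tmax at
#' minus/plus the diurnal half-range; radiation is the seasonal
#' clear-sky sinusoid scaled by `0.35 + 0.65 * u` with a fresh uniform
#' cloudiness draw each day, floored at 0.5 MJ m-2 d-1; rain occurrence
#' follows the two-state Markov chain with gamma wet-day amounts.
#'
#' @param clim a [climatology()].
#' @param start_date first day of the series.
#' @param n_days number of days (>= 1).
#' @param seed integer seed; the same seed reproduces the series
#'   exactly and the caller's RNG state is left untouched.
#' @return A [weather_series()].
#' @export
generate_weather <- function(clim = climatology(), start_date = "2004-09-01",
                             n_days = 365, seed = 1) {
  stopifnot(inherits(clim, "climatology"), n_days >= 1)
  with_local_seed(seed, {
    dates <- as.Date(start_date) + seq_len(n_days) - 1L
    doy <- as.integer(format(dates, "%j"))
    # temperature: minimum around 15 January (doy 15)
    t_det <- clim$annual_mean_temp -
      clim$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
    innov_sd <- clim$temp_noise_sd * sqrt(1 - clim$ar1_rho^2)
    anom <- as.numeric(stats::filter(
      stats::rnorm(n_days, sd = innov_sd), clim$ar1_rho,
      method = "recursive",
      init = stats::rnorm(1, sd = clim$temp_noise_sd)))
    tmean <- t_det + anom
    tmin <- tmean - clim$diurnal_half_range
    tmax <- tmean + clim$diurnal_half_range
    # radiation: clear-sky seasonal cycle (minimum near 21 December)
    r_clear <- pmax(0, clim$radiation_mean -
                      clim$radiation_amplitude *
                      cos(2 * pi * (doy + 10) / 365.25))
    cloud <- stats::runif(n_days)
    radiation <- pmax(0.5, r_clear * (0.35 + 0.65 * cloud))
    # rainfall: 2-state Markov occurrence, gamma amounts
    u <- stats::runif(n_days)
    wet <- logical(n_days)
    wet[1L] <- u[1L] < clim$rain_p_wet_dry
    for (t in 2L:n_days) {
      p <- if (wet[t - 1L]) clim$rain_p_wet_wet else clim$rain_p_wet_dry
      wet[t] <- u[t] < p
    }
    amounts <- stats::rgamma(n_days, shape = clim$rain_gamma_shape,
                             scale = clim$rain_gamma_mean /
                               clim$rain_gamma_shape)
    rain <- ifelse(wet, amounts, 0)
    weather_series(
      data.frame(date = dates, tmin_c = tmin, tmax_c = tmax,
                 radiation_mj_m2 = radiation, rain_mm = rain),
      latitude = clim$latitude)
  })
}

#' Preset climatologies
#'
#' `rothamsted_default` approximates the temperate-UK site climatology
#' (annual mean 9.8 deg C, seasonal amplitude 6.5 deg C, latitude
#' 51.8 N); `cold_year` and `warm_year` shift the annual mean by
#' -1.5 and +1.5 deg C to bracket the observed inter-annual range of
#' season warmth, which strongly modulates the competitive balance.
#'
#' @return named list of [climatology()] objects.
#' @export
preset_climatologies <- function() {
  list(rothamsted_default = climatology(),
       cold_year = climatology(annual_mean_temp = 9.8 - 1.5),
       warm_year = climatology(annual_mean_temp = 9.8 + 1.5))
}

#' Wheat cultivar trait fixtures
#'
#' Trait sets for three winter wheat cultivars with contrasting
#' competitive ability: Consort (the reference parameterisation),
#' Duxford (fast-developing, high specific leaf area - the strong weed
#' suppressor) and KWS Santiago (slower early growth - the weak
#' suppressor). Extinction coefficient 0.6 for all wheats.
#'
#' @return named list of [cultivar_traits()]: `consort`, `duxford`,
#'   `kws_santiago`.
#' @export
cultivar_fixtures <- function() {
  list(
    consort = cultivar_traits(
      name = "Consort", rwr = 0.71, ssa = 0.003, phyllochron = 90,
      sla = 0.019, rgr_ga = 0.0089, l0 = 0.64,
      height_a = 7.4, height_c = 77.9, height_b = 0.0085,
      height_m = 624, k_ext = 0.6),
    duxford = cultivar_traits(
      name = "Duxford", rwr = 0.705, ssa = 0.00545, phyllochron = 67.5,
      sla = 0.0385, rgr_ga = 0.0116, l0 = 0.674,
      height_a = 1.36, height_c = 81.845, height_b = 0.004218,
      height_m = 685.0, k_ext = 0.6),
    kws_santiago = cultivar_traits(
      name = "KWS Santiago", rwr = 0.681, ssa = 0.00504,
      phyllochron = 69.5, sla = 0.0346, rgr_ga = 0.0096, l0 = 0.715,
      height_a = 5.73, height_c = 77.299, height_b = 0.005559,
      height_m = 822.6, k_ext = 0.6)
  )
}

#' Default black-grass (Alopecurus myosuroides) trait set
#'
#' A documented stand-in parameterisation for the weed: faster
#' relative green-area growth than any of the wheat cultivars during
#' warm conditions (the weed's early-vigour advantage), a small
#' initial area, wheat-like specific leaf area, and a height curve
#' topping out just below the wheat canopy (heads held within the
#' crop). The weed's base temperature is 2 deg C against 0 for wheat:
#' the weed's thermal clocks slow relatively more in cool conditions,
#' so its competitive advantage is greatest in warm periods and is
#' eroded by delayed sowing into a colder emergence window. The
#' phyllochron places weed anthesis around early June for September
#' emergence. All values are configurable.
#'
#' @return a [cultivar_traits()].
#' @export
weed_traits_default <- function() {
  cultivar_traits(
    name = "A. myosuroides", rwr = 0.60, ssa = 0.004, phyllochron = 70,
    sla = 0.022, rgr_ga = 0.013, l0 = 0.30,
    height_a = 1, height_c = 75, height_b = 0.008, height_m = 550,
    k_ext = 0.5, t_base = 2)
}

#' Deterministic micro-scenarios for testing
#'
#' Named (config, weather) pairs exercising known-answer situations:
#' \describe{
#'   \item{constant}{220 days of constant mild weather (15 deg C mean,
#'     12 MJ m-2 d-1, 4 mm rain - above potential evapotranspiration,
#'     so water never limits), Consort at 250 plants m-2 with the
#'     standard 80 plants m-2 weed infestation.}
#'   \item{weed_free}{the same stand without the weed (yield loss must
#'     be exactly zero).}
#'   \item{symmetric}{crop and "weed" share identical traits, density
#'     and emergence lag - final above-ground biomasses must match.}
#'   \item{drought}{the constant scenario with zero rainfall - must
#'     yield less than its rain-fed twin.}
#' }
#'
#' @return named list of lists with elements `config` and `weather`.
#' @export
toy_scenarios <- function() {
  n <- 220
  dates <- as.Date("2020-09-01") + seq_len(n) - 1L
  base <- function(rain) weather_series(
    data.frame(date = dates, tmin_c = 10, tmax_c = 20,
               radiation_mj_m2 = 12, rain_mm = rain),
    latitude = 51.8)
  wet <- base(4)
  dry <- base(0)
  consort <- cultivar_fixtures()$consort
  list(
    constant = list(
      config = simulation_config(sowing_date = "2020-09-10",
                                 crop_density = 250, weed_density = 80,
                                 crop_traits = consort),
      weather = wet),
    weed_free = list(
      config = simulation_config(sowing_date = "2020-09-10",
                                 crop_density = 250, weed_density = 0,
                                 crop_traits = consort),
      weather = wet),
    symmetric = list(
      config = simulation_config(sowing_date = "2020-09-10",
                                 crop_density = 100, weed_density = 100,
                                 crop_emergence_lag = 8,
                                 weed_emergence_lag = 8,
                                 crop_traits = consort,
                                 weed_traits = consort),
      weather = wet),
    drought = list(
      config = simulation_config(sowing_date = "2020-09-10",
                                 crop_density = 250, weed_density = 80,
                                 crop_traits = consort),
      weather = dry)
  )
}
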