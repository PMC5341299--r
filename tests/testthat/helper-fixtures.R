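# shared fixtures: small deterministic weather and standard traits

constant_weather <- function(n = 220, start = "2020-09-01", tmin = 10,
                             tmax = 20, radiation = 12, rain = 2,
                             latitude = 51.8) {
  weather_series(
    data.frame(date = as.Date(start) + seq_len(n) - 1L,
               tmin_c = tmin, tmax_c = tmax,
               radiation_mj_m2 = radiation, rain_mm = rain),
    latitude = latitude)
}

weather_df <- function(n = 5, start = "2005-09-01") {
  data.frame(date = as.Date(start) + seq_len(n) - 1L,
             tmin_c = 5, tmax_c = 15, radiation_mj_m2 = 10, rain_mm = 0)
}

# ten replicate synthetic weather years over a common calendar window
weather_years <- function(n_years = 10, start = "2004-09-01") {
  ws <- lapply(seq_len(n_years), function(i) {
    generate_weather(seed = i, start_date = start, n_days = 365)
  })
  names(ws) <- paste0("year_", seq_len(n_years))
  ws
}

consort <- function() cultivar_fixtures()$consort
duxford <- function() cultivar_fixtures()$duxford
santiago <- function() cultivar_fixtures()$kws_santiago
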