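#' Configure a crop-weed season simulation
#'
#' @param sowing_date sowing date (`Date` or ISO string); both species
#'   are sown the same day and emerge after their lags.
#' @param crop_density crop plants m-2 (>= 0; 0 gives a weed-alone run
#'   whose season length is still set by the crop phenological clock).
#' @param weed_density weed plants m-2 (default 80, the standard
#'   infestation level used throughout the in-silico experiments).
#' @param crop_emergence_lag days from sowing to crop emergence
#'   (default 10).
#' @param weed_emergence_lag days from sowing to weed emergence
#'   (default 7).
#' @param crop_traits crop [cultivar_traits()].
#' @param weed_traits weed [cultivar_traits()] (default
#'   [weed_traits_default()]).
#' @param constants a [model_constants()].
#' @param latitude degrees north (default 51.8; used only if the
#'   weather series carries no latitude attribute).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(sowing_date, crop_density, weed_density = 80,
                              crop_emergence_lag = 10,
                              weed_emergence_lag = 7,
                              crop_traits,
                              weed_traits = weed_traits_default(),
                              constants = model_constants(),
                              latitude = 51.8) {
  stopifnot(inherits(crop_traits, "cultivar_traits"),
            inherits(weed_traits, "cultivar_traits"),
            inherits(constants, "model_constants"))
  if (crop_density < 0 || weed_density < 0) {
    stop("densities must be >= 0", call. = FALSE)
  }
  if (crop_emergence_lag < 0 || weed_emergence_lag < 0) {
    stop("emergence lags must be >= 0", call. = FALSE)
  }
  structure(list(sowing_date = as.Date(sowing_date),
                 crop_density = crop_density, weed_density = weed_density,
                 crop_emergence_lag = as.integer(crop_emergence_lag),
                 weed_emergence_lag = as.integer(weed_emergence_lag),
                 crop_traits = crop_traits, weed_traits = weed_traits,
                 constants = constants, latitude = latitude),
            class = "simulation_config")
}

# One season, one canopy composition (with or without the weed).
# Daily loop: advance clocks -> heights -> sink-limited exponential GAI
# (species independent) until total GAI reaches the switch (or the crop
# reaches anthesis, whichever is first) -> thereafter layered light
# partitioning, water balance, assimilation, partitioning and
# senescence/grain fill. Ends at crop maturity.
run_one <- function(config, weather, include_weed, trajectory = FALSE) {
  lat <- attr(weather, "latitude")
  if (is.null(lat)) lat <- config$latitude
  cn <- config$constants
  dates <- weather$date
  n <- length(dates)
  sow_idx <- match(as.Date(config$sowing_date), dates)
  if (is.na(sow_idx)) {
    stop("weather series does not cover the sowing date ",
         format(as.Date(config$sowing_date)), call. = FALSE)
  }
  doy <- as.integer(format(dates, "%j"))
  dl <- photoperiod(doy, lat)
  tmean <- (weather$tmin_c + weather$tmax_c) / 2
  par_in <- 0.5 * weather$radiation_mj_m2
  rad <- weather$radiation_mj_m2

  new_species <- function(traits, density, lag, has_grain) {
    dd <- pmax(0, tmean - traits$t_base)
    r_ref <- if (is.na(traits$r_ref)) cn$r_ref else traits$r_ref
    list(traits = traits, density = density,
         em = sow_idx + as.integer(lag),
         dd = dd, ptt_inc = dd * dl / 24,
         edd_inc = dd * pmin(1, rad / r_ref),
         tt = 0, ptt = 0, edd = 0,
         tt_anth = cn$final_leaf_number * traits$phyllochron,
         root = 0, leaf = 0, stem = 0, grain = 0, gai = 0,
         height = 0, in_repro = FALSE,
         anthesis_leafstem = 0, anthesis_gai = 0, relocated = 0,
         has_grain = has_grain,
         clock = list(leaf_number = 0))
  }
  crop <- new_species(config$crop_traits, config$crop_density,
                      config$crop_emergence_lag, has_grain = TRUE)
  weed <- new_species(config$weed_traits,
                      if (include_weed) config$weed_density else 0,
                      config$weed_emergence_lag, has_grain = FALSE)
  sp <- list(crop = crop, weed = weed)
  k_ext <- c(crop = config$crop_traits$k_ext,
             weed = config$weed_traits$k_ext)

  soil <- soil_water(cn$soil_capacity, cn$soil_capacity, cn$wilting_point)
  switched <- FALSE
  switch_idx <- NA_integer_
  end_idx <- NA_integer_
  tt_maturity <- sp$crop$tt_anth + cn$grain_fill_dd

  traj <- if (trajectory) vector("list", n - sow_idx + 1L) else NULL

  for (t in sow_idx:n) {
    # 1. biological clocks and heights
    for (s in names(sp)) {
      x <- sp[[s]]
      if (t >= x$em) {
        x$tt <- x$tt + x$dd[t]
        x$ptt <- x$ptt + x$ptt_inc[t]
        x$edd <- x$edd + x$edd_inc[t]
        x$clock$leaf_number <- x$tt / x$traits$phyllochron
        x$height <- height_at(x$ptt, x$traits)
        sp[[s]] <- x
      }
    }
    day <- list(radiation_mj_m2 = rad[t], rain_mm = weather$rain_mm[t])
    wf <- 1
    dm_day <- c(crop = 0, weed = 0)
    abs_day <- c(crop = 0, weed = 0)
    transmitted <- par_in[t]

    if (!switched) {
      # sink-limited: exponential green area, pools derived from area
      for (s in names(sp)) {
        x <- sp[[s]]
        if (t >= x$em && x$density > 0) {
          x$gai <- sink_limited_gai(x$traits, x$density, x$edd)
          x$leaf <- x$gai / x$traits$sla
          x$stem <- 0
          x$root <- x$leaf * x$traits$rwr / (1 - x$traits$rwr)
          x$grain <- 0
          sp[[s]] <- x
        }
      }
      total_gai <- sp$crop$gai + sp$weed$gai
      crop_at_anthesis <- t >= sp$crop$em && sp$crop$tt >= sp$crop$tt_anth
      if (competition_switch(total_gai, cn$gai_switch) || crop_at_anthesis) {
        switched <- TRUE
        switch_idx <- t
      }
    } else {
      active <- names(sp)[vapply(names(sp), function(s) {
        t >= sp[[s]]$em && sp[[s]]$density > 0 && sp[[s]]$gai > 0
      }, logical(1))]
      total_gai <- sp$crop$gai + sp$weed$gai
      part <- NULL
      if (length(active) > 0L) {
        stands <- lapply(active, function(s) {
          list(species = s, gai = sp[[s]]$gai, height = sp[[s]]$height)
        })
        layers <- build_layers(stands)
        part <- partition_light(layers, par_in[t], k_ext)
        transmitted <- part$transmitted
      }
      wres <- water_balance_step(soil, day, total_gai, cn)
      soil <- wres$soil
      wf <- wres$water_factor
      for (s in active) {
        x <- sp[[s]]
        absorbed <- part$absorbed[, s]
        dm <- daily_assimilation(absorbed, dl[t], cn, wf,
                                 green_area_per_layer = layers$area[, s])
        dm_day[s] <- dm
        abs_day[s] <- sum(absorbed)
        if (x$tt < x$tt_anth) {
          x <- partition_biomass(dm, x, x$traits, cn)
        } else {
          if (!x$in_repro) {
            x$in_repro <- TRUE
            x$anthesis_leafstem <- x$leaf + x$stem
            x$anthesis_gai <- x$gai
            x$relocated <- 0
          }
          tt_post <- x$tt - x$tt_anth
          if (x$has_grain) {
            x$grain <- x$grain + dm
            x <- senescence_grainfill_step(x, tt_post, cn)
          } else {
            x$stem <- x$stem + dm
            x$gai <- x$anthesis_gai *
              max(0, 1 - tt_post / cn$grain_fill_dd)
          }
        }
        sp[[s]] <- x
      }
    }

    if (trajectory) {
      traj[[t - sow_idx + 1L]] <- c(
        t = t, crop_gai = sp$crop$gai, weed_gai = sp$weed$gai,
        crop_height = sp$crop$height, weed_height = sp$weed$height,
        crop_leaf = sp$crop$leaf, crop_stem = sp$crop$stem,
        crop_root = sp$crop$root, crop_grain = sp$crop$grain,
        weed_leaf = sp$weed$leaf, weed_stem = sp$weed$stem,
        weed_root = sp$weed$root,
        par_in = par_in[t], crop_par = abs_day[["crop"]],
        weed_par = abs_day[["weed"]], transmitted = transmitted,
        crop_dm = dm_day[["crop"]], weed_dm = dm_day[["weed"]],
        soil_mm = soil$stored, water_factor = wf,
        switched = as.numeric(switched))
    }

    if (t >= sp$crop$em && sp$crop$tt >= tt_maturity) {
      end_idx <- t
      break
    }
  }
  if (is.na(end_idx)) {
    stop("weather series ends at ", format(dates[n]),
         " before crop maturity was reached", call. = FALSE)
  }

  traj_df <- NULL
  if (trajectory) {
    traj_df <- as.data.frame(do.call(rbind,
                                     traj[!vapply(traj, is.null, logical(1))]))
    traj_df$date <- dates[traj_df$t]
    traj_df$t <- NULL
  }
  list(grain = sp$crop$grain,
       crop_above_ground = sp$crop$leaf + sp$crop$stem + sp$crop$grain,
       weed_shoot = sp$weed$leaf + sp$weed$stem,
       season_mean_temp = mean(tmean[sow_idx:end_idx]),
       season_tt = sp$crop$tt,
       switch_date = if (is.na(switch_idx)) as.Date(NA) else dates[switch_idx],
       maturity_date = dates[end_idx],
       trajectory = traj_df)
}

#' Simulate one crop-weed season
#'
#' Runs the weedy season and, when both crop and weed are present, a
#' paired weed-free season on the same weather, from which percentage
#' yield loss is computed. The daily loop advances the thermal,
#' photothermal and effective-day-degree clocks, grows green area
#' exponentially (sink-limited) until the combined green area index
#' reaches the competition switch, then partitions light through the
#' layered mixed canopy, converts absorbed PAR to dry matter under the
#' soil water constraint, partitions biomass, and after anthesis
#' relocates reserves to grain while the canopy senesces. The season
#' ends at crop maturity.
#'
#' @param config a [simulation_config()].
#' @param weather a [weather_series()] covering sowing through crop
#'   maturity.
#' @param trajectory if `TRUE`, attach the daily state trajectory of
#'   the weedy run (data frame: green area, heights, pools, light
#'   fluxes, soil water).
#' @return A `simulation_result`: list with `grain_yield` and
#'   `weedfree_yield` (t ha-1), `yield_loss` (%), `weed_shoot_biomass`
#'   (g m-2 above-ground at crop maturity), `weed_seed_return`
#'   (seeds m-2), `crop_above_ground` (g m-2), `season_mean_temp`
#'   (deg C), `season_tt` (dd), `switch_date`, `maturity_date`, and
#'   optionally `trajectory`.
#' @export
run_season <- function(config, weather, trajectory = FALSE) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(weather, "weather_series"))
  has_weed <- config$weed_density > 0
  weedy <- run_one(config, weather, include_weed = has_weed,
                   trajectory = trajectory)
  cn <- config$constants
  if (config$crop_density > 0) {
    free <- if (has_weed) {
      run_one(config, weather, include_weed = FALSE)
    } else {
      weedy
    }
    weedfree_yield <- free$grain * 0.01   # g m-2 -> t ha-1
    if (weedfree_yield <= 0) {
      stop("weed-free run produced non-positive yield (",
           signif(weedfree_yield, 3), " t ha-1)", call. = FALSE)
    }
    grain_yield <- weedy$grain * 0.01
    loss <- if (has_weed) yield_loss(grain_yield, weedfree_yield) else 0
  } else {
    grain_yield <- NA_real_
    weedfree_yield <- NA_real_
    loss <- NA_real_
  }
  structure(list(
    grain_yield = grain_yield,
    weedfree_yield = weedfree_yield,
    yield_loss = loss,
    weed_shoot_biomass = weedy$weed_shoot,
    weed_seed_return = seed_return(weedy$weed_shoot, cn$seeds_per_gram),
    crop_above_ground = weedy$crop_above_ground,
    season_mean_temp = weedy$season_mean_temp,
    season_tt = weedy$season_tt,
    switch_date = weedy$switch_date,
    maturity_date = weedy$maturity_date,
    trajectory = weedy$trajectory
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  grain yield  %.2f t/ha (weed-free %.2f), yield loss %.1f %%\n",
              x$grain_yield, x$weedfree_yield, x$yield_loss))
  cat(sprintf("  weed shoot biomass %.1f g/m2, seed return %.0f /m2\n",
              x$weed_shoot_biomass, x$weed_seed_return))
  cat(sprintf("  canopy closed %s, mature %s, season tt %.0f dd\n",
              format(x$switch_date), format(x$maturity_date), x$season_tt))
  invisible(x)
}

#' Percentage yield loss
#'
#' `100 * (weedfree - weedy) / weedfree`.
#'
#' @param weedy,weedfree grain yields, t ha-1; `weedfree` must be > 0.
#' @return percentage yield loss.
#' @export
yield_loss <- function(weedy, weedfree) {
  if (any(weedfree <= 0)) stop("weedfree yield must be > 0", call. = FALSE)
  100 * (weedfree - weedy) / weedfree
}

#' Weed seed return from shoot biomass
#'
#' Seed production scales linearly with weed above-ground biomass at
#' maturity. The default coefficient (150 seeds g-1) is a calibration
#' choice placing a ~100 g m-2 biomass step at the order of 15,000
#' seeds m-2.
#'
#' @param weed_biomass g m-2 (>= 0).
#' @param seeds_per_gram seeds g-1.
#' @return seeds m-2.
#' @export
seed_return <- function(weed_biomass, seeds_per_gram = 150) {
  if (any(weed_biomass < 0)) stop("weed_biomass must be >= 0", call. = FALSE)
  seeds_per_gram * weed_biomass
}

#' Read a run configuration file
#'
#' YAML with sections `run` (sowing_date, crop_density, weed_density,
#' crop_emergence_lag, weed_emergence_lag, latitude), `crop` and `weed`
#' (trait tables keyed `name, rwr, ssa, phyllochron, sla, rgr_ga, l0,
#' height_a, height_c, height_b, height_m, k_ext`) and `constants`
#' (any [model_constants()] field). Missing `crop`/`weed`/`constants`
#' sections fall back to the Consort fixture, the default weed traits
#' and the default constants.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$run)) stop("config file has no 'run' section", call. = FALSE)
  crop <- if (is.null(cfg$crop)) cultivar_fixtures()$consort
          else do.call(cultivar_traits, cfg$crop)
  weed <- if (is.null(cfg$weed)) weed_traits_default()
          else do.call(cultivar_traits, cfg$weed)
  cons <- if (is.null(cfg$constants)) model_constants()
          else do.call(model_constants, cfg$constants)
  run <- cfg$run
  simulation_config(
    sowing_date = run$sowing_date,
    crop_density = run$crop_density,
    weed_density = if (is.null(run$weed_density)) 80 else run$weed_density,
    crop_emergence_lag = if (is.null(run$crop_emergence_lag)) 10
                         else run$crop_emergence_lag,
    weed_emergence_lag = if (is.null(run$weed_emergence_lag)) 7
                         else run$weed_emergence_lag,
    crop_traits = crop, weed_traits = weed, constants = cons,
    latitude = if (is.null(run$latitude)) 51.8 else run$latitude)
}
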