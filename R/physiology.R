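#' Model constants
#'
#' The species-independent constants of the simulator, all overridable:
#' \describe{
#'   \item{amax}{light-saturated assimilation ceiling per unit green
#'     area, g DM m-2 leaf h-1 (default 3.5; high enough that spring
#'     canopy growth is mainly light-limited, with saturation binding
#'     only around midday in bright weather).}
#'   \item{eps}{initial light-use efficiency, g DM per MJ absorbed PAR
#'     (default 3.0, a standard wheat radiation-use magnitude).}
#'   \item{gai_switch}{total green area index at which growth switches
#'     from sink- to source-limited (default 0.75).}
#'   \item{final_leaf_number}{phyllochron count at anthesis (default
#'     18: with a base temperature of 0 deg C and thermal time
#'     accumulated from autumn emergence through winter, 18
#'     phyllochrons place anthesis in May for the reference cultivar,
#'     as observed for UK winter wheat).}
#'   \item{grain_fill_dd}{thermal duration of grain filling /
#'     senescence, degree-days (default 750).}
#'   \item{relocation_fraction}{share of the leaf+stem biomass present
#'     at anthesis relocated to grain by maturity (default 0.25).}
#'   \item{r_ref}{reference radiation for effective day degrees,
#'     MJ m-2 d-1 (default 3: the radiation modifier slows the
#'     sink-limited leaf-area clock only in the darkest midwinter
#'     weeks, consistent with green-area expansion rates expressed per
#'     unit thermal time).}
#'   \item{pet_coefficient}{fraction of the radiation-equivalent
#'     evaporation realised as potential evapotranspiration
#'     (default 0.65).}
#'   \item{soil_capacity}{plant-available soil water store, mm
#'     (default 150).}
#'   \item{wilting_point}{lower bound of the store, mm (default 0).}
#'   \item{stress_threshold_fraction}{fraction of the available range
#'     below which the water stress factor ramps from 1 to 0
#'     (default 0.5).}
#'   \item{seeds_per_gram}{weed seeds produced per gram of weed shoot
#'     biomass at maturity (default 150).}
#' }
#'
#' @param amax,eps,gai_switch,final_leaf_number,grain_fill_dd,relocation_fraction,r_ref,pet_coefficient,soil_capacity,wilting_point,stress_threshold_fraction,seeds_per_gram see Description.
#' @return A `model_constants` object (named list).
#' @export
model_constants <- function(amax = 3.5, eps = 3.0, gai_switch = 0.75,
                            final_leaf_number = 18, grain_fill_dd = 750,
                            relocation_fraction = 0.25, r_ref = 3,
                            pet_coefficient = 0.65, soil_capacity = 150,
                            wilting_point = 0,
                            stress_threshold_fraction = 0.5,
                            seeds_per_gram = 150) {
  vals <- list(amax = amax, eps = eps, gai_switch = gai_switch,
               final_leaf_number = final_leaf_number,
               grain_fill_dd = grain_fill_dd,
               relocation_fraction = relocation_fraction, r_ref = r_ref,
               pet_coefficient = pet_coefficient,
               soil_capacity = soil_capacity, wilting_point = wilting_point,
               stress_threshold_fraction = stress_threshold_fraction,
               seeds_per_gram = seeds_per_gram)
  pos <- c("amax", "eps", "gai_switch", "final_leaf_number",
           "grain_fill_dd", "r_ref", "pet_coefficient", "soil_capacity",
           "stress_threshold_fraction", "seeds_per_gram")
  for (nm in pos) {
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0) {
      stop(nm, " must be positive and finite", call. = FALSE)
    }
  }
  if (wilting_point < 0 || wilting_point >= soil_capacity) {
    stop("wilting_point must satisfy 0 <= wilting_point < soil_capacity",
         call. = FALSE)
  }
  if (stress_threshold_fraction > 1) {
    stop("stress_threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  if (relocation_fraction < 0 || relocation_fraction >= 1) {
    stop("relocation_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(vals, class = "model_constants")
}

#' Soil water bucket state
#'
#' @param stored current plant-available water, mm.
#' @param capacity bucket capacity, mm.
#' @param wilting lower bound (wilting point), mm.
#' @return A `soil_water` object.
#' @export
soil_water <- function(stored, capacity = 150, wilting = 0) {
  if (wilting > stored || stored > capacity) {
    stop("soil water must satisfy wilting <= stored <= capacity",
         call. = FALSE)
  }
  structure(list(stored = stored, capacity = capacity, wilting = wilting),
            class = "soil_water")
}

# Gauss-Legendre nodes/weights on [0, 1], 3 points
.gauss3 <- list(
  nodes = c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15)),
  weights = c(5, 8, 5) / 18
)

#' Daily canopy assimilation from absorbed PAR
#'
#' Converts each layer's daily absorbed PAR to dry matter with a
#' saturating (negative-exponential) light response. For an
#' instantaneous absorbed flux `I` (MJ PAR m-2 ground h-1) falling on
#' green area `A` (m2 m-2) the rate is
#' `amax A (1 - exp(-eps I / (amax A)))` g DM m-2 ground h-1: the
#' light-saturated ceiling scales with the green area present, so the
#' result is invariant to subdividing a layer (splitting area and flux
#' proportionally), and at low light the response is linear with slope
#' `eps` whatever the area. When `green_area_per_layer` is omitted the
#' ceiling is `amax` per layer. The flux follows a sinusoidal diurnal
#' profile over the daylength and is integrated by 3-point
#' Gauss-Legendre quadrature, summed over layers, and scaled by the
#' water stress factor.
#'
#' @param absorbed_par_per_layer vector of daily absorbed PAR per canopy
#'   layer for one species, MJ m-2 d-1.
#' @param daylength hours of daylight.
#' @param constants a [model_constants()].
#' @param water_factor water stress multiplier in \[0, 1\].
#' @param green_area_per_layer the species' green area in each layer,
#'   m2 m-2 (same length as `absorbed_par_per_layer`); `NULL` for a
#'   unit-area ceiling per layer.
#' @return dry matter production, g DM m-2 d-1.
#' @export
daily_assimilation <- function(absorbed_par_per_layer, daylength,
                               constants, water_factor = 1,
                               green_area_per_layer = NULL) {
  I <- absorbed_par_per_layer
  if (any(I < 0)) stop("absorbed PAR must be >= 0", call. = FALSE)
  if (water_factor < 0 || water_factor > 1) {
    stop("water_factor must be in [0, 1]", call. = FALSE)
  }
  if (daylength <= 0 || length(I) == 0L || sum(I) == 0) return(0)
  A <- if (is.null(green_area_per_layer)) rep(1, length(I))
       else green_area_per_layer
  if (length(A) != length(I)) {
    stop("green_area_per_layer must match absorbed_par_per_layer",
         call. = FALSE)
  }
  keep <- I > 0 & A > 0
  I <- I[keep]; A <- A[keep]
  if (length(I) == 0L) return(0)
  cap <- constants$amax * A
  eps <- constants$eps
  total <- 0
  for (g in seq_along(.gauss3$nodes)) {
    # instantaneous flux at fractional daytime x: I_day * pi/(2D) sin(pi x)
    i_inst <- I * pi / (2 * daylength) * sin(pi * .gauss3$nodes[g])
    a_inst <- cap * (1 - exp(-eps * i_inst / cap))
    total <- total + .gauss3$weights[g] * sum(a_inst)
  }
  total * daylength * water_factor
}

#' One daily step of the soil water bucket
#'
#' Potential evapotranspiration is taken proportional to radiation
#' (`pet_coefficient * radiation / 2.45` mm, 2.45 MJ kg-1 being the
#' latent heat of vaporisation), split between soil evaporation
#' (`PET * exp(-0.5 GAI)`) and canopy transpiration demand
#' (`PET * (1 - exp(-0.5 GAI))`). Demand is met from the store plus the
#' day's rain, scaled down proportionally if the store would fall below
#' wilting; excess above capacity drains. The water stress factor ramps
#' linearly from 0 at wilting to 1 at `stress_threshold_fraction` of
#' the available range.
#'
#' @param soil a [soil_water()].
#' @param day single-day weather record (needs `radiation_mj_m2`,
#'   `rain_mm`).
#' @param total_gai combined green area index of the canopy.
#' @param constants a [model_constants()].
#' @return list with `soil` (updated [soil_water()]) and `water_factor`
#'   in \[0, 1\].
#' @export
water_balance_step <- function(soil, day, total_gai, constants) {
  stopifnot(inherits(soil, "soil_water"))
  pet <- constants$pet_coefficient * day$radiation_mj_m2 / 2.45
  evap <- pet * exp(-0.5 * total_gai)
  transp <- pet * (1 - exp(-0.5 * total_gai))
  supply <- soil$stored + day$rain_mm
  demand <- evap + transp
  available <- supply - soil$wilting
  actual <- if (demand > available) available else demand
  stored <- min(soil$capacity, supply - actual)
  stored <- max(soil$wilting, stored)
  range <- soil$capacity - soil$wilting
  wf <- (stored - soil$wilting) /
    (constants$stress_threshold_fraction * range)
  wf <- min(1, max(0, wf))
  list(soil = soil_water(stored, soil$capacity, soil$wilting),
       water_factor = wf)
}

#' Partition new dry matter among plant organs (vegetative phase)
#'
#' The fraction of new dry matter sent below ground declines linearly
#' with development from the trait `rwr` at emergence to 0.10 at
#' anthesis (development measured as leaf number over
#' `final_leaf_number`). The shoot fraction is all leaf before stem
#' extension (leaf number < 5); thereafter the leaf share of shoot
#' growth declines linearly to 0 at anthesis. Green area index is
#' recomputed from the updated pools as `sla * leaf + ssa * stem`.
#' Mass balance is exact: pool increments sum to `dm`.
#'
#' @param dm new dry matter, g m-2 d-1 (>= 0).
#' @param stand a stand state list with pools `root`, `leaf`, `stem`,
#'   `grain` (g m-2) and `clock` (a [pheno_clock()]).
#' @param traits the species' [cultivar_traits()].
#' @param constants a [model_constants()].
#' @return the stand with updated pools and `gai`.
#' @export
partition_biomass <- function(dm, stand, traits, constants) {
  if (dm < 0) stop("dm must be >= 0", call. = FALSE)
  ln <- stand$clock$leaf_number
  fln <- constants$final_leaf_number
  progress <- min(1, ln / fln)
  f_root <- if (ln < fln) traits$rwr + (0.10 - traits$rwr) * progress else 0
  shoot <- dm * (1 - f_root)
  leaf_share <- if (ln < 5) 1 else max(0, (fln - ln) / (fln - 5))
  stand$root <- stand$root + dm * f_root
  stand$leaf <- stand$leaf + shoot * leaf_share
  stand$stem <- stand$stem + shoot * (1 - leaf_share)
  stand$gai <- traits$sla * stand$leaf + traits$ssa * stand$stem
  stand
}

#' One daily step of senescence and grain filling
#'
#' After anthesis, a total of `relocation_fraction` of the leaf+stem
#' biomass present at anthesis is relocated to grain, spread uniformly
#' over `grain_fill_dd` of post-anthesis thermal time (drawn from leaf
#' and stem in proportion to their current size), and green area
#' declines linearly from its anthesis value to zero at maturity. The
#' grain pool is non-decreasing and no pool goes negative; relocation
#' moves mass without creating it.
#'
#' The stand must carry the anthesis snapshot fields
#' `anthesis_leafstem`, `anthesis_gai` and the cumulative `relocated`
#' (the season loop records these on the day anthesis is reached).
#'
#' @param stand a stand state list (see [partition_biomass()]) with the
#'   anthesis snapshot fields.
#' @param tt_post_anthesis accumulated thermal time since anthesis, dd.
#' @param constants a [model_constants()].
#' @return the updated stand.
#' @export
senescence_grainfill_step <- function(stand, tt_post_anthesis, constants) {
  if (tt_post_anthesis < 0) {
    stop("tt_post_anthesis must be >= 0", call. = FALSE)
  }
  frac_done <- min(1, tt_post_anthesis / constants$grain_fill_dd)
  target <- constants$relocation_fraction * stand$anthesis_leafstem *
    frac_done
  move <- max(0, target - stand$relocated)
  pool <- stand$leaf + stand$stem
  move <- min(move, pool)
  if (pool > 0 && move > 0) {
    stand$leaf <- stand$leaf - move * stand$leaf / pool
    stand$stem <- stand$stem - move * stand$stem / pool
    stand$grain <- stand$grain + move
    stand$relocated <- stand$relocated + move
  }
  stand$gai <- stand$anthesis_gai * (1 - frac_done)
  stand
}
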