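---
title: "Simulating wheat / black-grass canopy competition with weedcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating wheat / black-grass canopy competition with weedcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedcomp)
```

## The problem

*Alopecurus myosuroides* (black-grass) is the principal grass weed of
winter wheat in north-western Europe and has evolved resistance to most
of the herbicide classes used against it. The cultural levers left to a
grower - sowing the crop denser, sowing it later (allowing a stale
seedbed), and choosing a more competitive cultivar - are each known to
help on their own, but running the multi-year field factorials needed to
quantify their *combined* effect is prohibitively expensive. `weedcomp`
provides an eco-physiological simulator of one wheat / black-grass
season driven by daily weather, plus an experiment layer that runs
factorial grids of management scenarios across replicate weather years
and summarises them the way an agronomist would (means and standard
errors, balanced ANOVA with years as replicates, density-response
curves, cultural-equivalence solvers).

## The model

A season is simulated in daily time steps from sowing to crop maturity.
Both species are described by the same machinery with different trait
values; the weed is simply a second "cultivar" with its own parameters.

### Biological time

Three clocks accumulate per species from emergence (fixed lags after
sowing: 10 days for wheat, 7 for the weed):

* **Thermal time** `tt` (degree-days): daily mean temperature
  (arithmetic mean of tmin and tmax) above the species' base
  temperature.
* **Photothermal time** `ptt = dd * daylength / 24`: thermal time
  weighted by the civil daylength from the standard solar-declination
  formula. Height growth runs on this clock.
* **Effective day degrees** `edd = dd * min(1, radiation / r_ref)`:
  thermal time down-weighted when radiation is scarce. The early
  (sink-limited) leaf-area clock runs on this.

Development is indexed by leaf number (`tt` / phyllochron). Anthesis
occurs at `final_leaf_number` phyllochrons and maturity
`grain_fill_dd` degree-days later, so a cultivar with a shorter
phyllochron flowers at lower accumulated thermal time.

### Three growth phases

1. **Sink-limited expansion.** Until the combined green area index
   (GAI) of crop plus weed reaches `gai_switch` (0.75), each species'
   green area grows exponentially and independently:
   `GAI = density * L0 * exp(RGR_GA * edd)`. Area is the limiting
   resource here, so biomass pools are derived from area (leaf =
   GAI / SLA, roots at the trait root-weight ratio, no stem). This
   construction makes the trajectory continuous at the phase switch
   and guarantees that the weed's early trajectory is bit-for-bit
   independent of the crop - a property the test suite asserts at
   1e-12.
2. **Source-limited competition.** Once the canopy closes (or the crop
   reaches anthesis, whichever comes first - sparse weed-free stands
   can flower before closing), the mixed canopy is stratified into
   horizontal layers with boundaries at every distinct plant height,
   each species' area spread uniformly from the ground to its height.
   Light (PAR, taken as half of global radiation) is extinguished
   top-down by Beer's law; within a layer species absorb in proportion
   to `k * area`, which is the exact partition for uniformly mixed
   foliage. Absorbed PAR becomes dry matter through a saturating
   response integrated over a sinusoidal diurnal cycle by three-point
   Gauss-Legendre quadrature; the light-saturated ceiling scales with
   the green area present (`amax` per unit area), which makes the
   result invariant to how finely layers are subdivided. New dry
   matter is partitioned with a root fraction declining linearly from
   the trait RWR at emergence to 0.10 at anthesis, and a shoot split
   that is all leaf before stem extension (leaf 5) and shifts linearly
   to all stem by anthesis. GAI is recomputed from the pools
   (`SLA * leaf + SSA * stem`).
3. **Senescence and grain fill.** After anthesis a fixed fraction
   (`relocation_fraction`) of the leaf-plus-stem biomass present at
   anthesis is relocated to grain, spread uniformly over
   `grain_fill_dd`, while green area declines linearly to zero; net
   new assimilate also goes to grain. The weed has no grain organ in
   this model: after its own anthesis its assimilate goes to stem and
   its canopy senesces on the same schedule, and its "yield" is
   above-ground (leaf + stem) biomass at crop maturity, from which
   seed return is a linear multiple (`seeds_per_gram`, default 150).

A shared soil water bucket (default 150 mm plant-available, starting
full at sowing, appropriate for an autumn seedbed) loses potential
evapotranspiration proportional to radiation, split between soil
evaporation and transpiration by canopy cover; a stress factor ramps
assimilation down linearly once the store falls below half the
available range. Under the default temperate climatology water rarely
limits; the module matters for dry-spring scenarios and is exercised by
the drought toy scenario.

Percentage yield loss compares the weedy run with a paired weed-free
run on the same weather; the pair differs only in weed density, so any
weed trait value leaves the control untouched.

## Parameter choices that matter

* **`r_ref` = 3 MJ m-2 d-1.** The radiation modifier on the
  sink-phase clock bites only in the darkest midwinter weeks. This is
  deliberate: green-area expansion rates of the cultivars are
  expressed per unit thermal time, and with a high reference level the
  modifier would stall autumn canopy development until spring, which
  contradicts how a September-sown wheat canopy actually closes (our
  default stands pass GAI 0.75 in November-December).
* **`final_leaf_number` = 18 phyllochrons.** With base temperature
  0 degC and thermal time accumulated from autumn emergence through
  winter (the model has no vernalisation or photoperiod-gene module),
  18 phyllochrons place anthesis in May for the reference cultivar -
  the right phenology for UK winter wheat on these clocks. The value
  is a development *target expressed in phyllochron units* rather than
  a literal count of leaves.
* **`amax` = 3.5 g DM m-2 leaf h-1.** High enough that spring growth
  is mostly light-limited; saturation binds only around midday in
  bright weather. With a much lower ceiling, dry-matter production
  becomes proportional to green area rather than light, which lets
  small historical area differences compound independently of actual
  weed pressure.
* **The weed trait set** is a constructed stand-in (no published
  parameter table exists for this pairing in the sources available to
  the package) built around three mechanisms: (i) a base temperature
  of 2 degC against wheat's 0, so the weed's growth advantage is
  concentrated in warm periods and is eroded when late sowing pushes
  its establishment into a colder window; (ii) a relative green-area
  growth rate (0.013 per EDD) above every cultivar's, giving the weed
  its early-vigour edge in a warm autumn; (iii) wheat-like leaf
  economics (SLA 0.022 m2 g-1) and a height curve topping out at
  75 cm - heads held within the canopy - with anthesis around early
  June. Earlier drafts of this parameterisation with a much higher
  weed SLA or a later, taller weed let the weed drift to a
  density-independent share of light late in the season, which erased
  the very management signals the simulator exists to study; the
  current set keeps the competitive outcome anchored to the
  autumn/winter share of the canopy, where sowing rate, sowing date
  and cultivar actually act.

All of these are ordinary arguments (`model_constants()`,
`cultivar_traits()`) and can be changed per run.

## The synthetic weather generator

`generate_weather()` emulates a temperate maritime site at 51.8 N:
a seasonal temperature sinusoid (annual mean 9.8 degC, half-range
6.5 degC, minimum in mid-January) with stationary AR(1) anomalies
(rho 0.7, sd 2 degC), a fixed 8 degC diurnal range, radiation as a
clear-sky seasonal sinusoid scaled by a daily uniform cloudiness draw,
and rainfall from a two-state Markov chain (P(wet|wet) 0.6, P(wet|dry)
0.3) with gamma amounts (shape 0.8, mean 4 mm). Replicate "years" are
independent seeds over a common September-August calendar window,
matching the assumption that yearly weather records are temporally
independent. The generator reproduces the *statistical texture* the
simulator needs - autumn warmth vs winter cold, dim Novembers and
bright Aprils, wet and dry spells - but it is not fitted to any
observed station record: persistent blocking events, cold springs
following mild winters, and radiation-temperature correlations are not
represented. Passing the package's directional tests therefore shows
that the mechanisms respond correctly to realistic weather statistics,
not that the model reproduces any particular site's history.

## Numerical choices

* Daylength uses the civil convention (sun centre at -0.833 degrees),
  clamped to [0, 24] for polar latitudes.
* Light conservation is exact by construction (each layer passes on
  what it does not intercept); the suite checks it to 1e-9 daily.
* The diurnal integral uses 3-point Gauss-Legendre on the daylight
  interval; against a 1000-step reference it agrees to better than 1%
  over the whole operating range.
* Layer boundaries are placed at every distinct stand height; exact
  height ties simply merge boundaries. A stand with positive area but
  zero height is rejected.
* The sink-to-source switch latches: once the canopy has closed it
  stays closed even if senescence later drops total GAI below 0.75.
* The rectangular-hyperbola fit starts from the linearisation
  `1/loss ~ density` and polishes by Levenberg-Marquardt; an exact
  start (flat or noiseless data) short-circuits the optimiser.
* ANOVA is computed by explicit balanced-design sums of squares
  (unbalanced tables are rejected rather than silently reordered);
  interaction terms subtract lower-order terms recursively.
* Equivalence solvers invert fitted monotone curves (hyperbola over
  density, linear-in-days over sowing date) rather than raw cell
  means, and flag any answer outside the simulated range as
  extrapolated.

## Problem sizes

The bundled experiments use the layouts the package treats as
standard: a 49-cell grid (densities 100-400 by 50, sowing dates
15 September to 14 November by 10 days) for the reference cultivar, a
2 x 2 x 2 cultivar x density x date factorial, both over ten replicate
weather years; density-equivalence curves span 100-600 plants m-2 and
date-equivalence curves 20 September to 20 October. One paired season
(weedy plus control) takes on the order of 0.1 s, so the full battery
runs in a couple of minutes on a single core.

## Known limitations

* Below-ground competition is only implicit (a shared water bucket and
  a root allocation fraction); nitrogen is absent. Predictions where
  soil resources dominate should not be trusted.
* The weed parameter set is a mechanistic stand-in, so absolute yield
  losses are indicative; the package's value is in *relative*
  comparisons across management scenarios.
* Reduced weed establishment at late sowing dates is deliberately not
  modelled; the late-sowing benefit shown is therefore conservative.
* Single weed cohort, single weed species, no herbicide module.
* Cultivar phenology is tied to the phyllochron, which exaggerates
  flowering-date differences between cultivars relative to the field.

## A worked season

```{r example, eval = FALSE}
library(weedcomp)

weather <- generate_weather(seed = 1, start_date = "2004-09-01")
cfg <- simulation_config(
  sowing_date = "2004-09-20", crop_density = 300,
  crop_traits = cultivar_fixtures()$consort)
run_season(cfg, weather)

# a small factorial over three weather years
years <- lapply(1:3, function(i) generate_weather(seed = i,
                                                  start_date = "2004-09-01"))
grid <- factorial_grid(
  densities = c(150, 300),
  sowing_dates = as.Date(c("2004-09-20", "2004-10-20")),
  cultivars = cultivar_fixtures()[c("duxford", "kws_santiago")],
  weather_set = years)
tab <- run_factorial(grid)
summarize_results(tab, c("cultivar", "sowing_date"), "yield_loss")
anova_factorial(tab, "yield_loss", c("cultivar", "density", "sowing_date"))
```
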