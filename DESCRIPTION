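Package: weedcomp
Title: Eco-Physiological Simulation of Crop-Weed Canopy Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily time-step simulation of competition for light between
    winter wheat and the grass weed Alopecurus myosuroides (black-grass),
    built around multi-layer Beer's-law light partitioning of a mixed
    canopy, thermal/photothermal phenology, sink- and source-limited
    growth phases, a soil water bucket, and grain filling. Includes a
    seeded stochastic weather generator emulating temperate UK
    climatology, trait sets for contrasting wheat cultivars, and an
    in-silico experiment layer (factorial grids over sowing density,
    sowing date, cultivar and weather year, balanced-design ANOVA,
    rectangular-hyperbola density responses and cultural-equivalence
    solvers) for quantifying non-chemical weed control levers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
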