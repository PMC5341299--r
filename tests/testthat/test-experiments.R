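# small synthetic results table with known structure (no simulation)
synthetic_table <- function(n_years = 10, seed = 99) {
  set.seed(seed)
  grid <- expand.grid(year = paste0("y", seq_len(n_years)),
                      cultivar = c("a", "b"), density = c(150, 300),
                      sowing_date = as.Date(c("2004-09-20", "2004-10-20")),
                      stringsAsFactors = FALSE)
  grid$yield_loss <- 10 + 5 * (grid$cultivar == "b") -
    0.01 * grid$density + rnorm(nrow(grid))
  grid$weed_biomass <- 20 * grid$yield_loss + rnorm(nrow(grid), sd = 5)
  grid
}

test_that("factorial grids enumerate cells completely and in order", {
  ws <- list(a = constant_weather(220), b = constant_weather(220))
  g <- factorial_grid(densities = c(150, 300),
                      sowing_dates = as.Date(c("2020-09-10", "2020-09-20")),
                      cultivars = list(consort = consort()),
                      weather_set = ws)
  tab <- run_factorial(g)
  expect_equal(nrow(tab), 2 * 1 * 2 * 2)
  expect_equal(names(tab),
               c("year", "cultivar", "density", "sowing_date", "yield_loss",
                 "weed_biomass", "weedfree_yield", "seed_return",
                 "season_mean_temp", "season_tt"))
  expect_false(any(is.na(tab$yield_loss)))
  # re-running reproduces the table exactly
  expect_identical(tab, run_factorial(g))

  g1 <- factorial_grid(densities = 150,
                       sowing_dates = as.Date("2020-09-10"),
                       cultivars = list(consort = consort()),
                       weather_set = ws[1])
  expect_equal(nrow(run_factorial(g1)), 1)
  expect_error(factorial_grid(densities = numeric(0),
                              sowing_dates = as.Date("2020-09-10"),
                              cultivars = list(consort()),
                              weather_set = ws), "densities")
})

test_that("group summaries give the textbook mean and standard error", {
  tab <- data.frame(g = c("x", "x", "x", "y", "y", "y"),
                    v = c(2, 4, 6, 5, 5, 5))
  s <- summarize_results(tab, "g", "v")
  expect_equal(s$mean, c(4, 5))
  expect_equal(s$se, c(2 / sqrt(3), 0))
  expect_equal(s$n, c(3, 3))
  # balanced groups: grand mean equals the mean of group means
  expect_equal(mean(s$mean), mean(tab$v))
  expect_error(summarize_results(tab, "nope", "v"), "nope")
})

test_that("explicit sums of squares reproduce the reference linear model", {
  tab <- synthetic_table()
  an <- anova_factorial(tab, "yield_loss",
                        c("cultivar", "density", "sowing_date"))
  # residual df for a 2x2x2 main-effects model with 10 replicate years
  expect_equal(an$df[an$effect == "residual"], 76)
  ref <- anova(lm(yield_loss ~ factor(cultivar) + factor(density) +
                    factor(sowing_date), data = tab))
  expect_equal(an$ss[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(an$ss[an$effect == "residual"], ref$`Sum Sq`[4],
               tolerance = 1e-8)
  expect_equal(an$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(an$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
  # SS decomposition is exact
  expect_equal(sum(an$ss[an$effect %in%
                           c("cultivar", "density", "sowing_date",
                             "residual")]),
               an$ss[an$effect == "total"], tolerance = 1e-8)

  # full interaction decomposition against the reference model
  an2 <- anova_factorial(tab, "yield_loss",
                         c("cultivar", "density", "sowing_date"),
                         interactions = TRUE)
  ref2 <- anova(lm(yield_loss ~ factor(cultivar) * factor(density) *
                     factor(sowing_date), data = tab))
  expect_equal(sort(an2$ss[1:7]), sort(ref2$`Sum Sq`[1:7]),
               tolerance = 1e-8)

  # degenerate and invalid inputs
  const <- tab; const$yield_loss <- 5
  an3 <- anova_factorial(const, "yield_loss", c("cultivar", "density"))
  expect_equal(an3$ss[an3$effect == "total"], 0)
  expect_true(all(is.na(an3$F[1:2])))
  expect_error(anova_factorial(tab[-1, ], "yield_loss",
                               c("cultivar", "density")), "balanced")
})

test_that("rectangular hyperbola fitting recovers known parameters", {
  d <- seq(50, 600, by = 50)
  yl <- 50 / (1 + 0.01 * d)
  fit <- fit_hyperbola(d, yl)
  expect_equal(fit$A, 50, tolerance = 1e-6)
  expect_equal(fit$B, 0.01, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # fitted curve strictly decreasing when B > 0
  expect_true(all(diff(fit$fitted(seq(10, 1000, 10))) < 0))

  flat <- fit_hyperbola(d, rep(12, length(d)))
  expect_equal(flat$B, 0, tolerance = 1e-6)
  expect_equal(flat$A, 12, tolerance = 1e-4)
  expect_error(fit_hyperbola(c(100, 100, 100), c(1, 2, 3)), "distinct")
  expect_error(fit_hyperbola(d, -yl), "> 0")
})

test_that("equivalence solvers invert constructed response curves", {
  dens <- seq(100, 600, by = 100)
  years <- paste0("y", 1:3)
  curve_a <- function(d) 60 / (1 + 0.02 * d)   # stronger cultivar
  curve_b <- function(d) 30 / (1 + 0.02 * d)
  tab <- expand.grid(year = years, cultivar = c("a", "b"), density = dens,
                     stringsAsFactors = FALSE)
  tab$yield_loss <- ifelse(tab$cultivar == "a",
                           curve_b(tab$density), curve_a(tab$density))
  # cultivar "b" is the weaker one (higher loss curve_a)
  # target: loss of a at 300 = 30/7 ; b matches when 60/(1+0.02d) = 30/7
  eq <- equivalent_density(tab, "a", 300, "b")
  expect_equal(eq$target_loss, 30 / 7, tolerance = 1e-6)
  expect_equal(eq$density, (60 * 7 / 30 - 1) / 0.02, tolerance = 1e-4)
  expect_true(eq$extrapolated)   # 650 is beyond the 600 maximum

  # self-equivalence returns the reference density
  self <- equivalent_density(tab, "a", 250, "a")
  expect_equal(self$density, 250, tolerance = 1e-6)
  expect_false(self$extrapolated)

  # dates: linear decreasing curves with a known crossing
  dates <- as.Date("2004-09-20") + seq(0, 40, 10)
  tab2 <- expand.grid(year = years, cultivar = c("a", "b"),
                      sowing_date = dates, stringsAsFactors = FALSE)
  day <- as.numeric(tab2$sowing_date - dates[1])
  tab2$yield_loss <- ifelse(tab2$cultivar == "a",
                            10 - 0.2 * day, 20 - 0.3 * day)
  # a at +10 days: loss 8; b reaches 8 at day 40
  ed <- equivalent_date(tab2, "a", dates[2], "b")
  expect_equal(ed$date, dates[1] + 40)
  expect_false(ed$extrapolated)
  expect_equal(equivalent_date(tab2, "a", dates[2], "a")$date, dates[2])
  # crossing outside the simulated window is flagged
  tab3 <- tab2
  tab3$yield_loss <- ifelse(tab3$cultivar == "a",
                            5 - 0.1 * day, 40 - 0.1 * day)
  ed3 <- equivalent_date(tab3, "a", dates[1], "b")
  expect_true(ed3$extrapolated)
  # non-monotone response errors
  tab4 <- tab2
  tab4$yield_loss[tab4$cultivar == "b" &
                    tab4$sowing_date == dates[5]] <- 50
  expect_error(equivalent_date(tab4, "a", dates[2], "b"),
               "not strictly decreasing")
})

test_that("loss-biomass correlation matches a hand computation", {
  lin <- data.frame(yield_loss = 1:5, weed_biomass = 2 * (1:5) + 3)
  expect_equal(loss_biomass_correlation(lin)$r, 1, tolerance = 1e-12)
  anti <- data.frame(yield_loss = 1:5, weed_biomass = 10 - 2 * (1:5))
  expect_equal(loss_biomass_correlation(anti)$r, -1, tolerance = 1e-12)

  x <- c(3, 8, 1, 9, 4); y <- c(10, 35, 8, 30, 14)
  # explicit sum formulation of Pearson's r
  r_hand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) *
           (sum(y^2) - length(x) * mean(y)^2))
  got <- loss_biomass_correlation(
    data.frame(yield_loss = x, weed_biomass = y))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_lt(got$p, 0.05)
  expect_error(loss_biomass_correlation(
    data.frame(yield_loss = rep(1, 5), weed_biomass = 1:5)),
    "zero variance")
})
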