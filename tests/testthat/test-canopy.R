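test_that("trait constructor enforces physical invariants", {
  expect_s3_class(consort(), "cultivar_traits")
  mk <- function(...) {
    args <- utils::modifyList(
      list(name = "x", rwr = 0.7, ssa = 0.003, phyllochron = 90,
           sla = 0.019, rgr_ga = 0.009, l0 = 0.6, height_a = 7,
           height_c = 78, height_b = 0.008, height_m = 620),
      list(...))
    do.call(cultivar_traits, args)
  }
  expect_error(mk(rwr = 1.2), "rwr")
  expect_error(mk(sla = 0.002), "sla")
  expect_error(mk(height_a = 90), "height_a")
  expect_error(mk(rgr_ga = -1), "positive")
})

test_that("logistic height curve: midpoint, asymptote, monotone", {
  con <- consort()
  # midpoint of the logistic is (a + c)/2
  expect_equal(height_at(624, con), (7.4 + 77.9) / 2, tolerance = 1e-12)
  expect_equal(height_at(624, con), 42.65)
  expect_equal(height_at(1e7, con), 77.9, tolerance = 1e-6)
  # frozen direct evaluation for Duxford at emergence
  expect_equal(height_at(0, duxford()), 5.60023, tolerance = 1e-4)
  # strictly increasing, bounded by the asymptote
  h <- height_at(seq(0, 3000, by = 10), con)
  expect_true(all(diff(h) > 0))
  expect_true(all(h < con$height_c))
})

test_that("sink-limited green area is exponential in effective day degrees", {
  con <- consort()
  expect_equal(sink_limited_gai(con, 250, 0), 0.016)
  expect_equal(sink_limited_gai(con, 250, 300), 0.016 * exp(0.0089 * 300),
               tolerance = 1e-12)
  expect_equal(sink_limited_gai(con, 250, 300), 0.231045, tolerance = 1e-4)
  # linear in density
  expect_equal(sink_limited_gai(con, 500, 123),
               2 * sink_limited_gai(con, 250, 123), tolerance = 1e-12)
})

test_that("competition switch threshold is a sharp boundary", {
  expect_false(competition_switch(0))
  expect_false(competition_switch(0.74))
  expect_true(competition_switch(0.75))
  expect_true(competition_switch(0.76, threshold = 0.75))
  expect_error(competition_switch(-0.1), ">= 0")
})

test_that("canopy layering conserves per-species green area", {
  one <- build_layers(list(list(species = "a", gai = 2, height = 50)))
  expect_equal(one$z_low, 0)
  expect_equal(one$z_high, 50)
  expect_equal(unname(one$area[1, "a"]), 2)

  two <- build_layers(list(list(species = "a", gai = 1.2, height = 40),
                           list(species = "b", gai = 0.8, height = 80)))
  expect_equal(two$z_low, c(0, 40))
  expect_equal(two$z_high, c(40, 80))
  expect_equal(unname(two$area[2, "a"]), 0)         # only taller in top
  expect_equal(unname(two$area[2, "b"]), 0.4)       # half of b's height
  expect_equal(colSums(two$area), c(a = 1.2, b = 0.8), tolerance = 1e-12)

  expect_error(
    build_layers(list(list(species = "a", gai = 1, height = 0))),
    "zero height")

  # conservation on random mixed stands
  set.seed(7)
  for (i in 1:20) {
    stands <- lapply(1:3, function(j) {
      list(species = paste0("s", j), gai = runif(1, 0, 6),
           height = runif(1, 5, 120))
    })
    lay <- build_layers(stands)
    expect_equal(unname(colSums(lay$area)),
                 vapply(stands, `[[`, numeric(1), "gai"),
                 tolerance = 1e-12)
  }
})

# independent fine-discretisation oracle: Beer's law through n_sub thin
# slices per layer, species area uniform within its height
fine_partition <- function(stands, i0, k_ext, n_sub = 1000) {
  top <- max(vapply(stands, `[[`, numeric(1), "height"))
  z <- seq(top, 0, length.out = n_sub + 1L)
  absorbed <- setNames(numeric(length(stands)),
                       vapply(stands, `[[`, character(1), "species"))
  I <- i0
  for (i in seq_len(n_sub)) {
    dz <- z[i] - z[i + 1L]
    ka <- vapply(stands, function(s) {
      dens <- if (z[i] <= s$height) s$gai / s$height else 0
      k_ext[[s$species]] * dens * dz
    }, numeric(1))
    tot <- sum(ka)
    if (tot > 0) {
      inter <- I * (1 - exp(-tot))
      absorbed <- absorbed + inter * ka / tot
      I <- I - inter
    }
  }
  list(absorbed_total = absorbed, transmitted = I)
}

test_that("Beer's-law partitioning: closed form, symmetry, conservation", {
  k <- c(crop = 0.6, weed = 0.5)
  empty <- build_layers(list(list(species = "crop", gai = 0, height = 50),
                             list(species = "weed", gai = 0, height = 30)))
  p0 <- partition_light(empty, 10, k)
  expect_equal(p0$transmitted, 10)

  # single species closed form
  single <- build_layers(list(list(species = "crop", gai = 2, height = 60)))
  p1 <- partition_light(single, 8, k)
  expect_equal(unname(p1$absorbed_total["crop"]), 8 * (1 - exp(-1.2)),
               tolerance = 1e-12)

  # identical twins split light exactly in half
  twins <- build_layers(list(list(species = "crop", gai = 1.5, height = 70),
                             list(species = "weed", gai = 1.5, height = 70)))
  p2 <- partition_light(twins, 10, c(crop = 0.55, weed = 0.55))
  expect_equal(unname(p2$absorbed_total["crop"]),
               unname(p2$absorbed_total["weed"]), tolerance = 1e-12)

  # conservation and agreement with the 1000-sub-layer oracle
  set.seed(11)
  for (i in 1:10) {
    stands <- list(
      list(species = "crop", gai = runif(1, 0.5, 6), height = runif(1, 30, 90)),
      list(species = "weed", gai = runif(1, 0.1, 3), height = runif(1, 10, 70)))
    lay <- build_layers(stands)
    p <- partition_light(lay, 10, k)
    expect_equal(sum(p$absorbed_total) + p$transmitted, 10,
                 tolerance = 1e-9)
    fine <- fine_partition(stands, 10, as.list(k))
    expect_equal(unname(p$absorbed_total), unname(fine$absorbed_total),
                 tolerance = 5e-3)
  }
})

test_that("at equal GAI, the taller species never absorbs less", {
  k <- c(a = 0.6, b = 0.6)
  share_a <- function(h_a) {
    lay <- build_layers(list(list(species = "a", gai = 2, height = h_a),
                             list(species = "b", gai = 2, height = 60)))
    partition_light(lay, 10, k)$absorbed_total[["a"]]
  }
  shares <- vapply(seq(20, 120, by = 10), share_a, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})
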