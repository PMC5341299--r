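#' Define a factorial in-silico experiment grid
#'
#' The cross of crop densities x sowing dates x cultivars, run over a
#' set of replicate weather years at a fixed weed infestation. The
#' default experiment layout used throughout the package mirrors the
#' standard design: densities in 50 plants m-2 steps, sowing dates in
#' 10-day steps, weed density 80 plants m-2, emergence lags of 10
#' (crop) and 7 (weed) days.
#'
#' @param densities crop densities, plants m-2 (non-empty, positive).
#' @param sowing_dates `Date` vector of sowing dates (non-empty).
#' @param cultivars named list of [cultivar_traits()] (non-empty).
#' @param weather_set list of [weather_series()], one per replicate
#'   year; names (or indices) become the year ids.
#' @param weed_density fixed weed density, plants m-2.
#' @param crop_emergence_lag,weed_emergence_lag days.
#' @param weed_traits weed [cultivar_traits()].
#' @param constants a [model_constants()].
#' @return A `factorial_grid` object.
#' @export
factorial_grid <- function(densities, sowing_dates, cultivars, weather_set,
                           weed_density = 80, crop_emergence_lag = 10,
                           weed_emergence_lag = 7,
                           weed_traits = weed_traits_default(),
                           constants = model_constants()) {
  if (length(densities) == 0L || any(densities <= 0)) {
    stop("densities must be a non-empty vector of positive values",
         call. = FALSE)
  }
  if (length(sowing_dates) == 0L) stop("sowing_dates is empty", call. = FALSE)
  if (length(cultivars) == 0L) stop("cultivars is empty", call. = FALSE)
  if (length(weather_set) == 0L) stop("weather_set is empty", call. = FALSE)
  if (is.null(names(cultivars))) {
    names(cultivars) <- vapply(cultivars, function(x) x$name, character(1))
  }
  if (is.null(names(weather_set))) {
    names(weather_set) <- paste0("year_", seq_along(weather_set))
  }
  structure(list(densities = densities,
                 sowing_dates = as.Date(sowing_dates),
                 cultivars = cultivars, weather_set = weather_set,
                 weed_density = weed_density,
                 crop_emergence_lag = crop_emergence_lag,
                 weed_emergence_lag = weed_emergence_lag,
                 weed_traits = weed_traits, constants = constants),
            class = "factorial_grid")
}

#' Run a factorial grid of season simulations
#'
#' One [run_season()] per cell x year, in deterministic order (years
#' outermost, then cultivars, densities, dates). The result is the
#' long-format results table feeding [summarize_results()],
#' [anova_factorial()] and the equivalence solvers.
#'
#' @param grid a [factorial_grid()].
#' @return data frame with one row per cell x year and columns `year`,
#'   `cultivar`, `density`, `sowing_date`, `yield_loss` (%),
#'   `weed_biomass` (g m-2), `weedfree_yield` (t ha-1), `seed_return`
#'   (m-2), `season_mean_temp` (deg C), `season_tt` (dd).
#' @export
run_factorial <- function(grid) {
  stopifnot(inherits(grid, "factorial_grid"))
  rows <- vector("list",
                 length(grid$weather_set) * length(grid$cultivars) *
                   length(grid$densities) * length(grid$sowing_dates))
  i <- 0L
  for (yr in names(grid$weather_set)) {
    weather <- grid$weather_set[[yr]]
    for (cv in names(grid$cultivars)) {
      for (dens in grid$densities) {
        for (d in seq_along(grid$sowing_dates)) {
          sow <- grid$sowing_dates[d]
          config <- simulation_config(
            sowing_date = sow, crop_density = dens,
            weed_density = grid$weed_density,
            crop_emergence_lag = grid$crop_emergence_lag,
            weed_emergence_lag = grid$weed_emergence_lag,
            crop_traits = grid$cultivars[[cv]],
            weed_traits = grid$weed_traits,
            constants = grid$constants)
          res <- tryCatch(run_season(config, weather), error = function(e) {
            stop("run_season failed for year=", yr, " cultivar=", cv,
                 " density=", dens, " date=", format(sow), ": ",
                 conditionMessage(e), call. = FALSE)
          })
          i <- i + 1L
          rows[[i]] <- data.frame(
            year = yr, cultivar = cv, density = dens,
            sowing_date = sow, yield_loss = res$yield_loss,
            weed_biomass = res$weed_shoot_biomass,
            weedfree_yield = res$weedfree_yield,
            seed_return = res$weed_seed_return,
            season_mean_temp = res$season_mean_temp,
            season_tt = res$season_tt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means and standard errors
#'
#' Mean and standard error (sd / sqrt(n)) of a response within each
#' combination of grouping factors, typically over replicate weather
#' years.
#'
#' @param table a results table (e.g. from [run_factorial()]).
#' @param group_by character vector of grouping column names.
#' @param response response column name.
#' @return data frame of the grouping columns plus `mean`, `se`, `n`.
#' @export
summarize_results <- function(table, group_by, response) {
  missing_cols <- setdiff(c(group_by, response), names(table))
  if (length(missing_cols) > 0L) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  key <- interaction(table[group_by], drop = TRUE, lex.order = TRUE)
  split_y <- split(table[[response]], key)
  if (any(vapply(split_y, length, integer(1)) == 0L)) {
    stop("empty group", call. = FALSE)
  }
  first <- !duplicated(key)
  out <- table[first, group_by, drop = FALSE]
  out <- out[order(key[first]), , drop = FALSE]
  out$mean <- vapply(split_y, mean, numeric(1))
  out$se <- vapply(split_y, function(y) {
    if (length(y) > 1L) stats::sd(y) / sqrt(length(y)) else 0
  }, numeric(1))
  out$n <- vapply(split_y, length, numeric(1))
  rownames(out) <- NULL
  out
}

# balanced-design sum of squares for a subset of factors:
# SS over the subset's cell means minus all lower-order terms
.ss_subset <- function(y, fac_df, subset, grand, ss_cache) {
  key <- interaction(fac_df[subset], drop = TRUE, lex.order = TRUE)
  means <- tapply(y, key, mean)
  counts <- tapply(y, key, length)
  ss_cells <- sum(counts * (means - grand)^2)
  lower <- 0
  if (length(subset) > 1L) {
    for (sz in seq_len(length(subset) - 1L)) {
      for (combo in utils::combn(subset, sz, simplify = FALSE)) {
        lower <- lower + ss_cache[[paste(combo, collapse = ":")]]
      }
    }
  }
  ss_cells - lower
}

#' Factorial ANOVA by explicit sums of squares
#'
#' Analysis of variance for a balanced complete factorial with
#' replicate runs (e.g. weather years) as residual replication. Main
#' effect sums of squares are computed explicitly from level means;
#' with `interactions = TRUE` all interaction terms are added via the
#' standard balanced-design decomposition (cell SS minus lower-order
#' terms). F ratios use the residual mean square; p-values come from
#' the F distribution. Unbalanced tables are rejected (main-effect
#' sums of squares would be order-dependent).
#'
#' @param table results table.
#' @param response response column name.
#' @param factors character vector of factor column names (each with
#'   >= 2 levels).
#' @param interactions include interaction terms (default `FALSE`:
#'   main effects only).
#' @return data frame with columns `effect`, `df`, `ss`, `ms`, `F`,
#'   `p` (residual and total rows included; `F`/`p` are `NA` for a
#'   constant response).
#' @export
anova_factorial <- function(table, response, factors,
                            interactions = FALSE) {
  missing_cols <- setdiff(c(response, factors), names(table))
  if (length(missing_cols) > 0L) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(factors) < 1L) stop("need at least one factor", call. = FALSE)
  y <- table[[response]]
  fac_df <- lapply(table[factors], function(f) factor(f))
  fac_df <- as.data.frame(fac_df, stringsAsFactors = TRUE)
  n_levels <- vapply(fac_df, nlevels, integer(1))
  if (any(n_levels < 2L)) {
    stop("every factor needs >= 2 levels; offending: ",
         paste(factors[n_levels < 2L], collapse = ", "), call. = FALSE)
  }
  cell <- interaction(fac_df, drop = FALSE, lex.order = TRUE)
  counts <- table(cell)
  if (length(unique(as.integer(counts))) != 1L || any(counts == 0L)) {
    stop("design is not a balanced complete factorial: cell counts ",
         paste(range(counts), collapse = "-"), call. = FALSE)
  }
  n <- length(y)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  df_total <- n - 1L

  subsets <- lapply(factors, function(f) f)
  if (interactions && length(factors) > 1L) {
    for (sz in 2:length(factors)) {
      subsets <- c(subsets, utils::combn(factors, sz, simplify = FALSE))
    }
  }
  ss_cache <- list()
  effects <- character(0); dfs <- numeric(0); sss <- numeric(0)
  for (subset in subsets) {
    nm <- paste(subset, collapse = ":")
    ss <- .ss_subset(y, fac_df, subset, grand, ss_cache)
    ss_cache[[nm]] <- ss
    effects <- c(effects, nm)
    dfs <- c(dfs, prod(n_levels[subset] - 1L))
    sss <- c(sss, ss)
  }
  df_res <- df_total - sum(dfs)
  ss_res <- ss_total - sum(sss)
  if (df_res <= 0) {
    stop("no residual degrees of freedom left for this model",
         call. = FALSE)
  }
  ms_res <- ss_res / df_res
  ms <- sss / dfs
  if (ss_total > 0 && ms_res > 0) {
    f_stat <- ms / ms_res
    p <- stats::pf(f_stat, dfs, df_res, lower.tail = FALSE)
  } else {
    f_stat <- rep(NA_real_, length(ms))
    p <- rep(NA_real_, length(ms))
  }
  out <- data.frame(
    effect = c(effects, "residual", "total"),
    df = c(dfs, df_res, df_total),
    ss = c(sss, ss_res, ss_total),
    ms = c(ms, ms_res, NA_real_),
    F = c(f_stat, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a rectangular hyperbola to a density response
#'
#' Diminishing-returns yield-loss response to crop density:
#' `loss(d) = A / (1 + B d)`, fitted by nonlinear least squares with a
#' start from the linearisation `1/loss ~ d`. With `B > 0` the curve
#' is strictly decreasing in density; `B ~ 0` captures a flat
#' response.
#'
#' @param densities crop densities (>= 3 distinct values).
#' @param yield_losses corresponding losses (> 0).
#' @return list with `A`, `B`, `rss` and `fitted` (a function of
#'   density).
#' @export
fit_hyperbola <- function(densities, yield_losses) {
  if (length(unique(densities)) < 3L) {
    stop("need >= 3 distinct densities", call. = FALSE)
  }
  if (length(densities) != length(yield_losses)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(yield_losses <= 0)) {
    stop("yield losses must be > 0 for the hyperbolic fit", call. = FALSE)
  }
  lin <- stats::lm(I(1 / yield_losses) ~ densities)
  a0 <- 1 / max(stats::coef(lin)[1L], 1e-8)
  b0 <- max(stats::coef(lin)[2L] * a0, 0)
  rss0 <- sum((yield_losses - a0 / (1 + b0 * densities))^2)
  if (rss0 <= 1e-20 * sum(yield_losses^2)) {
    # the linearised start already fits exactly (flat or noiseless data)
    return(list(A = unname(a0), B = unname(b0), rss = rss0,
                fitted = function(d) a0 / (1 + b0 * d)))
  }
  dat <- data.frame(d = densities, yl = yield_losses)
  fit <- tryCatch(
    minpack.lm::nlsLM(yl ~ A / (1 + B * d), data = dat,
                      start = list(A = a0, B = b0),
                      lower = c(A = 1e-10, B = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("hyperbola fit did not converge (start A=", signif(a0, 4),
           ", B=", signif(b0, 4), "): ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); B <- unname(cf["B"])
  list(A = A, B = B,
       rss = sum(stats::resid(fit)^2),
       fitted = function(d) A / (1 + B * d))
}

# mean loss per (cultivar, axis level), averaged over years (and any
# other factors present), from a long results table
.mean_curve <- function(table, cultivar, axis) {
  sub <- table[table$cultivar == cultivar, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("cultivar not in table: ", cultivar, call. = FALSE)
  }
  agg <- summarize_results(sub, group_by = axis, response = "yield_loss")
  agg[order(agg[[axis]]), , drop = FALSE]
}

#' Crop density at which one cultivar matches another's yield loss
#'
#' Finds the stand density at which `other_cultivar` achieves the same
#' mean yield loss as `ref_cultivar` sown at `ref_density`, by
#' inverting rectangular-hyperbola fits ([fit_hyperbola()]) of each
#' cultivar's mean density-loss curve. A result beyond the simulated
#' density range is returned with `extrapolated = TRUE`. Errors if the
#' fitted response is not strictly decreasing in density.
#'
#' @param table results table from [run_factorial()].
#' @param ref_cultivar,ref_density the reference cultivar and its
#'   density.
#' @param other_cultivar the cultivar whose density is solved for.
#' @return list with `density`, `target_loss`, `extrapolated`.
#' @export
equivalent_density <- function(table, ref_cultivar, ref_density,
                               other_cultivar) {
  ref_curve <- .mean_curve(table, ref_cultivar, "density")
  oth_curve <- .mean_curve(table, other_cultivar, "density")
  ref_fit <- fit_hyperbola(ref_curve$density, ref_curve$mean)
  oth_fit <- fit_hyperbola(oth_curve$density, oth_curve$mean)
  if (oth_fit$B <= 0) {
    stop("density response of ", other_cultivar,
         " is not decreasing (fitted B <= 0)", call. = FALSE)
  }
  target <- ref_fit$fitted(ref_density)
  if (target <= 0 || target >= oth_fit$A) {
    stop("target loss ", signif(target, 4),
         " is outside the invertible range of the fitted hyperbola",
         call. = FALSE)
  }
  d <- (oth_fit$A / target - 1) / oth_fit$B
  list(density = d, target_loss = target,
       extrapolated = d < min(oth_curve$density) ||
         d > max(oth_curve$density))
}

#' Sowing date at which one cultivar matches another's yield loss
#'
#' As [equivalent_density()] but along the sowing-date axis, using
#' linear-in-days interpolation of each cultivar's mean date-loss
#' curve (which must be strictly decreasing with later sowing). A
#' crossing outside the simulated window is linearly extrapolated and
#' flagged.
#'
#' @param table results table from [run_factorial()].
#' @param ref_cultivar,ref_date reference cultivar and sowing date.
#' @param other_cultivar the cultivar whose sowing date is solved for.
#' @return list with `date` (a `Date`), `target_loss`, `extrapolated`.
#' @export
equivalent_date <- function(table, ref_cultivar, ref_date,
                            other_cultivar) {
  ref_curve <- .mean_curve(table, ref_cultivar, "sowing_date")
  oth_curve <- .mean_curve(table, other_cultivar, "sowing_date")
  for (curve in list(ref_curve, oth_curve)) {
    if (any(diff(curve$mean) >= 0)) {
      stop("mean yield loss is not strictly decreasing with sowing date",
           call. = FALSE)
    }
  }
  ref_date <- as.Date(ref_date)
  ref_x <- as.numeric(ref_curve$sowing_date)
  target <- stats::approx(ref_x, ref_curve$mean, xout = as.numeric(ref_date),
                          rule = 2)$y
  oth_x <- as.numeric(oth_curve$sowing_date)
  extrapolated <- target > max(oth_curve$mean) || target < min(oth_curve$mean)
  if (!extrapolated) {
    x <- stats::approx(oth_curve$mean, oth_x, xout = target)$y
  } else {
    # linear extrapolation from the nearest segment
    if (target > max(oth_curve$mean)) {
      i <- c(1L, 2L)
    } else {
      i <- c(nrow(oth_curve) - 1L, nrow(oth_curve))
    }
    slope <- (oth_curve$mean[i[2L]] - oth_curve$mean[i[1L]]) /
      (oth_x[i[2L]] - oth_x[i[1L]])
    x <- oth_x[i[1L]] + (target - oth_curve$mean[i[1L]]) / slope
  }
  list(date = as.Date(round(x), origin = "1970-01-01"),
       target_loss = target, extrapolated = extrapolated)
}

#' Correlation between yield loss and weed biomass
#'
#' Pearson correlation (with a two-sided test) of percentage yield
#' loss against weed above-ground biomass across all rows of a results
#' table. The two quantities are alternative measures of competitive
#' outcome and are expected to be strongly positively correlated.
#'
#' @param table results table with columns `yield_loss` and
#'   `weed_biomass` (>= 3 rows).
#' @return list with `r` and `p`.
#' @export
loss_biomass_correlation <- function(table) {
  if (nrow(table) < 3L) stop("need >= 3 rows", call. = FALSE)
  x <- table$yield_loss
  y <- table$weed_biomass
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in yield_loss or weed_biomass", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
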