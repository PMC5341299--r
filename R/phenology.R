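#' Create a phenological clock
#'
#' Per-species biological time since emergence: accumulated thermal time
#' (`tt`, degree-days), photothermal time (`ptt`) and effective day
#' degrees (`edd`), plus the derived leaf number (`tt / phyllochron`).
#' All clocks start at zero at emergence and are non-decreasing.
#'
#' @param tt,ptt,edd initial accumulated values (default 0).
#' @param phyllochron thermal time per leaf, dd leaf-1 (used to derive
#'   leaf number).
#' @return A `pheno_clock` object.
#' @export
pheno_clock <- function(tt = 0, ptt = 0, edd = 0, phyllochron) {
  stopifnot(tt >= 0, ptt >= 0, edd >= 0, phyllochron > 0)
  structure(list(tt = tt, ptt = ptt, edd = edd, phyllochron = phyllochron,
                 leaf_number = tt / phyllochron),
            class = "pheno_clock")
}

#' Advance a phenological clock by one day
#'
#' Adds the day's thermal, photothermal and effective-day-degree
#' increments (see the weather module) and recomputes leaf number.
#'
#' @param clock a [pheno_clock()].
#' @param day a single-row weather record (list or one-row data frame
#'   with `date`, `tmin_c`, `tmax_c`, `radiation_mj_m2`).
#' @param traits the species' [cultivar_traits()] (supplies `t_base`).
#' @param latitude site latitude, degrees north.
#' @param r_ref reference radiation for effective day degrees.
#' @return the advanced `pheno_clock`.
#' @export
advance_clock <- function(clock, day, traits, latitude = 51.8, r_ref = 10) {
  stopifnot(inherits(clock, "pheno_clock"))
  if (!is.null(traits$r_ref) && !is.na(traits$r_ref)) r_ref <- traits$r_ref
  dd <- thermal_time_increment(day$tmin_c, day$tmax_c, traits$t_base)
  doy <- as.integer(format(as.Date(day$date), "%j"))
  dl <- photoperiod(doy, latitude)
  clock$tt <- clock$tt + dd
  clock$ptt <- clock$ptt + photothermal_increment(dd, dl)
  clock$edd <- clock$edd +
    effective_day_degrees_increment(dd, day$radiation_mj_m2, r_ref)
  clock$leaf_number <- clock$tt / clock$phyllochron
  clock
}

#' Emergence date from sowing date and a fixed lag
#'
#' @param sowing_date a `Date`.
#' @param lag_days non-negative integer lag (default lags elsewhere in
#'   the package: 10 days for wheat, 7 for black-grass).
#' @return a `Date`.
#' @export
emergence_day <- function(sowing_date, lag_days) {
  if (lag_days < 0) stop("lag_days must be >= 0", call. = FALSE)
  as.Date(sowing_date) + as.integer(lag_days)
}

#' Developmental stage of an emerged plant stand
#'
#' Stage switches are driven by the thermal clock: anthesis (start of the
#' reproductive phase) when leaf number reaches `final_leaf_number`,
#' i.e. at `final_leaf_number * phyllochron` degree-days after
#' emergence, and maturity after a further `grain_fill_dd` degree-days.
#' A cultivar with a shorter phyllochron therefore reaches anthesis at
#' lower accumulated thermal time. Pre-emergence is handled by the
#' season loop (a clock only exists once the stand has emerged).
#'
#' @param clock a [pheno_clock()].
#' @param traits the species' [cultivar_traits()].
#' @param constants a [model_constants()] list (supplies
#'   `final_leaf_number` and `grain_fill_dd`).
#' @return one of `"vegetative"`, `"reproductive"`, `"mature"`.
#' @export
stage_of <- function(clock, traits, constants) {
  tt_anthesis <- constants$final_leaf_number * traits$phyllochron
  if (clock$tt < tt_anthesis) {
    "vegetative"
  } else if (clock$tt < tt_anthesis + constants$grain_fill_dd) {
    "reproductive"
  } else {
    "mature"
  }
}
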