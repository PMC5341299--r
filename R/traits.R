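#' Construct a species / cultivar trait set
#'
#' The eco-physiological parameters that distinguish wheat cultivars (or
#' the weed) in the competition model: early-growth traits (initial green
#' area `l0`, relative growth rate of green area `rgr_ga` per effective
#' degree-day), leaf economics (`sla`, `ssa`: green area per unit leaf and
#' stem dry mass), allocation (`rwr`: fraction of new dry matter sent
#' below ground at emergence), development speed (`phyllochron`:
#' degree-days per leaf), the logistic height curve against photothermal
#' time (`height_a` initial, `height_c` asymptote, `height_b` rate,
#' `height_m` inflexion) and the Beer's-law extinction coefficient
#' `k_ext`.
#'
#' @param name species or cultivar name.
#' @param rwr root weight ratio at emergence, dimensionless in (0, 1).
#' @param ssa specific stem area, m2 g-1.
#' @param phyllochron thermal time per leaf appearance, dd leaf-1.
#' @param sla specific leaf area, m2 g-1 (must exceed `ssa`).
#' @param rgr_ga relative growth rate of green area per effective
#'   degree-day (sink-limited phase).
#' @param l0 initial green area per plant at emergence, cm2.
#' @param height_a initial height, cm.
#' @param height_c height asymptote, cm (must exceed `height_a`).
#' @param height_b logistic rate constant, per photothermal unit.
#' @param height_m photothermal time at the inflexion point.
#' @param k_ext light extinction coefficient (default 0.6, typical for
#'   wheat canopies).
#' @param t_base base temperature for all thermal clocks, degrees C.
#' @param r_ref species radiation level (MJ m-2 d-1) at which the
#'   effective-day-degree radiation modifier saturates; `NA` (default)
#'   defers to the run's [model_constants()] value. A small value makes
#'   the species' early growth effectively temperature-limited only
#'   (shade-tolerant establishment).
#' @return A `cultivar_traits` object (named list).
#' @export
cultivar_traits <- function(name, rwr, ssa, phyllochron, sla, rgr_ga, l0,
                            height_a, height_c, height_b, height_m,
                            k_ext = 0.6, t_base = 0, r_ref = NA_real_) {
  num <- c(rwr = rwr, ssa = ssa, phyllochron = phyllochron, sla = sla,
           rgr_ga = rgr_ga, l0 = l0, height_a = height_a,
           height_c = height_c, height_b = height_b, height_m = height_m,
           k_ext = k_ext)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all trait parameters must be positive and finite; offending: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (rwr >= 1) stop("rwr must be < 1", call. = FALSE)
  if (height_a >= height_c) stop("height_a must be < height_c", call. = FALSE)
  if (sla <= ssa) stop("sla must exceed ssa", call. = FALSE)
  if (!is.finite(t_base)) stop("t_base must be finite", call. = FALSE)
  if (!is.na(r_ref) && r_ref <= 0) stop("r_ref must be > 0", call. = FALSE)
  structure(
    list(name = name, rwr = rwr, ssa = ssa, phyllochron = phyllochron,
         sla = sla, rgr_ga = rgr_ga, l0 = l0, height_a = height_a,
         height_c = height_c, height_b = height_b, height_m = height_m,
         k_ext = k_ext, t_base = t_base, r_ref = r_ref),
    class = "cultivar_traits")
}

#' @export
print.cultivar_traits <- function(x, ...) {
  cat(sprintf("<cultivar_traits> %s\n", x$name))
  cat(sprintf("  RWR %.3f | SSA %.5f | SLA %.4f m2 g-1 | phyllochron %.1f dd\n",
              x$rwr, x$ssa, x$sla, x$phyllochron))
  cat(sprintf("  RGR_GA %.4f EDD-1 | L0 %.3f cm2 | k %.2f | t_base %.1f C\n",
              x$rgr_ga, x$l0, x$k_ext, x$t_base))
  cat(sprintf("  height: a %.2f -> c %.2f cm, b %.5f ptt-1, m %.1f ptt\n",
              x$height_a, x$height_c, x$height_b, x$height_m))
  invisible(x)
}
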