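#' Plant height from photothermal time
#'
#' Logistic height growth
#' `h(ptt) = a + (c - a) / (1 + exp(-b (ptt - m)))`: strictly
#' increasing in photothermal time, bounded above by the asymptote `c`.
#' Height determines which canopy layers a species occupies and hence
#' its access to light at the top of a mixed canopy.
#'
#' @param ptt accumulated photothermal time (>= 0, vectorised).
#' @param traits a [cultivar_traits()] (supplies `height_a`, `height_c`,
#'   `height_b`, `height_m`).
#' @return height in cm.
#' @export
height_at <- function(ptt, traits) {
  if (any(ptt < 0)) stop("ptt must be >= 0", call. = FALSE)
  traits$height_a + (traits$height_c - traits$height_a) /
    (1 + exp(-traits$height_b * (ptt - traits$height_m)))
}

#' Sink-limited green area index
#'
#' During early growth, before the canopy closes, green area expands
#' exponentially with effective day degrees, independent of assimilate
#' supply: `GAI = density * L0[m2] * exp(RGR_GA * edd)` with the initial
#' per-plant green area `l0` converted from cm2 to m2.
#'
#' @param traits a [cultivar_traits()].
#' @param density plants m-2 (>= 0).
#' @param edd accumulated effective day degrees since emergence (>= 0).
#' @return green area index, m2 m-2.
#' @export
sink_limited_gai <- function(traits, density, edd) {
  if (any(edd < 0)) stop("edd must be >= 0", call. = FALSE)
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  density * traits$l0 * 1e-4 * exp(traits$rgr_ga * edd)
}

#' Sink-to-source competition switch
#'
#' Growth changes from the sink-limited exponential phase to
#' source-limited light competition once the combined green area index
#' of all stands reaches a threshold (default 0.75). The switch is a
#' pure threshold test; the season loop latches it (once the canopy has
#' closed it stays closed).
#'
#' @param total_gai combined GAI of all species, m2 m-2 (>= 0).
#' @param threshold switch GAI (default 0.75).
#' @return logical.
#' @export
competition_switch <- function(total_gai, threshold = 0.75) {
  if (any(total_gai < 0)) stop("total_gai must be >= 0", call. = FALSE)
  total_gai >= threshold
}

#' Stratify a mixed canopy into horizontal layers
#'
#' Layer boundaries are placed at height zero and at every distinct
#' stand height. Each species' green area is distributed uniformly from
#' the ground to its height, so its area in a layer is proportional to
#' the layer thickness within its height. Per-species area is conserved
#' across layers exactly.
#'
#' @param stands a list of stands, each a list with `species` (name),
#'   `gai` (m2 m-2) and `height` (cm).
#' @return A `canopy_layers` object: list with `z_low`, `z_high`
#'   (vectors, bottom to top) and `area`, a layers x species matrix of
#'   green area (m2 m-2).
#' @export
build_layers <- function(stands) {
  gai <- vapply(stands, function(s) s$gai, numeric(1))
  height <- vapply(stands, function(s) s$height, numeric(1))
  species <- vapply(stands, function(s) s$species, character(1))
  if (any(gai < 0)) stop("stand GAI must be >= 0", call. = FALSE)
  if (any(gai > 0 & height <= 0)) {
    stop("stand with positive GAI but zero height: ",
         paste(species[gai > 0 & height <= 0], collapse = ", "),
         call. = FALSE)
  }
  active <- gai > 0
  if (!any(active)) {
    out <- list(z_low = numeric(0), z_high = numeric(0),
                area = matrix(0, 0, length(species),
                              dimnames = list(NULL, species)))
    class(out) <- "canopy_layers"
    return(out)
  }
  bounds <- sort(unique(c(0, height[active])))
  n_layer <- length(bounds) - 1L
  area <- matrix(0, n_layer, length(species),
                 dimnames = list(NULL, species))
  for (j in seq_along(species)) {
    if (!active[j]) next
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1L]
    frac <- (pmin(hi, height[j]) - pmin(lo, height[j])) / height[j]
    area[, j] <- gai[j] * frac
  }
  out <- list(z_low = bounds[-length(bounds)], z_high = bounds[-1L],
              area = area)
  class(out) <- "canopy_layers"
  out
}

#' Partition light through a layered mixed canopy
#'
#' Beer's law applied top-down through the layers. In a layer with
#' per-species green areas `A_s` and extinction coefficients `k_s`, the
#' fraction `1 - exp(-sum(k_s A_s))` of the incoming flux is
#' intercepted, and each species takes the share
#' `k_s A_s / sum(k_j A_j)` (the exact split for species mixed
#' uniformly within the layer). What a layer transmits enters the layer
#' below; light is conserved exactly:
#' `sum(absorbed) + transmitted == i0`.
#'
#' @param layers a `canopy_layers` object from [build_layers()].
#' @param i0 incident flux above the canopy (e.g. MJ PAR m-2 d-1,
#'   >= 0).
#' @param k_ext named vector of extinction coefficients, one per species
#'   column of `layers$area`.
#' @return list with `absorbed` (layers x species matrix, same row
#'   order as `layers`, bottom to top), `absorbed_total` (named
#'   per-species vector) and `transmitted` (flux reaching the soil).
#' @export
partition_light <- function(layers, i0, k_ext) {
  stopifnot(inherits(layers, "canopy_layers"))
  if (i0 < 0) stop("i0 must be >= 0", call. = FALSE)
  area <- layers$area
  if (any(area < 0)) stop("negative layer green area", call. = FALSE)
  species <- colnames(area)
  k <- k_ext[species]
  if (any(is.na(k))) {
    stop("missing extinction coefficient for: ",
         paste(species[is.na(k)], collapse = ", "), call. = FALSE)
  }
  n_layer <- nrow(area)
  absorbed <- matrix(0, n_layer, length(species),
                     dimnames = dimnames(area))
  i_in <- i0
  if (n_layer > 0L) {
    for (l in seq(n_layer, 1L)) {       # top layer first
      ka <- k * area[l, ]
      ka_sum <- sum(ka)
      if (ka_sum > 0) {
        intercepted <- i_in * (1 - exp(-ka_sum))
        absorbed[l, ] <- intercepted * ka / ka_sum
        i_in <- i_in - intercepted
      }
    }
  }
  list(absorbed = absorbed,
       absorbed_total = colSums(absorbed),
       transmitted = i_in)
}
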