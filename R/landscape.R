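#' Shannon diversity of land-cover proportions
#'
#' H = -sum(p_i log p_i) over the classes present (p_i > 0), in nats by
#' default.
#'
#' @param class_proportions Non-negative proportions summing to 1
#'   (within 1e-6).
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @return H >= 0.
#' @export
#' @examples
#' shannon_diversity(rep(0.25, 4))  # log(4)
shannon_diversity <- function(class_proportions, base = exp(1)) {
  p <- class_proportions
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Shannon evenness of land-cover proportions
#'
#' E = H / log(S) with S the number of classes present; defined as 0
#' for a single-class landscape (no heterogeneity to apportion).
#'
#' @inheritParams shannon_diversity
#' @return E in \[0, 1\].
#' @export
shannon_evenness <- function(class_proportions, base = exp(1)) {
  p <- class_proportions
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  s <- sum(p > 0)
  if (s <= 1) return(0)
  shannon_diversity(p, base = base) / log(s, base = base)
}

#' The eight landscape indicators of one unit
#'
#' Computes, from a land-cover raster: water/total, land/total and
#' saltmarsh/total area ratios (water = brackish + freshwater),
#' freshwater/brackish and land/saltmarsh area ratios, total saltmarsh
#' perimeter over saltmarsh area in km per km2, and the Shannon
#' diversity and evenness of the class proportions. Zero-denominator
#' ratios are returned as NA (flagged undefined, excluded pairwise
#' downstream) rather than 0.
#'
#' @param raster An [lc_raster()] with at least one non-nodata pixel.
#' @param connectivity Patch connectivity for the perimeter, 4 or 8.
#' @return One-row data.frame with the columns of
#'   [landscape_indicator_names()].
#' @export
compute_landscape_indicators <- function(raster, connectivity = 4) {
  stopifnot(inherits(raster, "lc_raster"))
  a_land <- class_area(raster, 1L)
  a_marsh <- class_area(raster, 2L)
  a_brack <- class_area(raster, 3L)
  a_fresh <- class_area(raster, 4L)
  total <- a_land + a_marsh + a_brack + a_fresh
  if (total == 0) stop("raster has no non-nodata pixels")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  marsh_patches <- label_patches(raster, 2L, connectivity = connectivity)
  perim_m <- sum(marsh_patches$patches$n_edges) * raster$pixel_size
  # m / m2 -> km / km2 is a factor 1000
  pa <- if (a_marsh == 0) NA_real_ else (perim_m / a_marsh) * 1000
  props <- c(a_land, a_marsh, a_brack, a_fresh) / total
  data.frame(
    water_total = (a_brack + a_fresh) / total,
    land_total = a_land / total,
    saltmarsh_total = a_marsh / total,
    freshwater_brackish = ratio(a_fresh, a_brack),
    land_saltmarsh = ratio(a_land, a_marsh),
    saltmarsh_perimeter_area = pa,
    shannon_diversity = shannon_diversity(props),
    shannon_evenness = shannon_evenness(props)
  )
}

#' Landscape indicator table for a whole scenario
#'
#' @param scenario A [generate_scenario()] object.
#' @return data.frame with `legend_id`, `group` and the eight indicator
#'   columns, one row per unit.
#' @export
landscape_indicator_table <- function(scenario) {
  stopifnot(inherits(scenario, "valli_scenario"))
  rows <- lapply(scenario$units, function(u) {
    cbind(data.frame(legend_id = u$unit$legend_id, group = u$unit$group),
          compute_landscape_indicators(u$raster))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
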