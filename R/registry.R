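#' Land-cover legend
#'
#' Class codes used by every [lc_raster()] grid: 0 = nodata (outside the
#' unit embankment), 1 = terrestrial land, 2 = saltmarsh, 3 = brackish
#' water, 4 = freshwater. "Water" in the landscape indicators means
#' brackish + freshwater.
#'
#' @return Named integer vector of the five legend codes.
#' @export
#' @examples
#' lc_legend()
lc_legend <- function() {
  c(nodata = 0L, land = 1L, saltmarsh = 2L, brackish = 3L, freshwater = 4L)
}

#' Management group labels
#'
#' The five management strategies of the valli da pesca: F = fish
#' production (extensive aquaculture), M = multiple ESs, H = hunting,
#' R = recreational activities, N = not managed.
#'
#' @return Character vector `c("F","M","H","R","N")`.
#' @export
management_groups <- function() c("F", "M", "H", "R", "N")

#' Ecosystem-service registry
#'
#' The nine assessed ecosystem services and their CICES category.
#' Climate regulation and water purification have capacity identically
#' equal to flow; the three cultural capacities are dimensionless
#' attractiveness indices on a 0-1 scale.
#'
#' @return A data.frame with columns `es`, `category`, `capacity_unit`,
#'   `flow_unit`.
#' @export
#' @examples
#' es_registry()
es_registry <- function() {
  data.frame(
    es = c("climate_regulation", "water_purification", "lifecycle_support",
           "aquaculture", "hunting", "wild_food",
           "tourism", "cognitive_development", "birdwatching"),
    category = rep(c("regulating", "provisioning", "cultural"), each = 3),
    capacity_unit = c("gC m-2 y-1", "% N load removed", "index 0-1",
                      "kg ha-1 y-1", "n ha-1 y-1", "kg ha-1 y-1",
                      "index 0-1", "index 0-1", "index 0-1"),
    flow_unit = c("gC m-2 y-1", "% N load removed", "index 0-2",
                  "kg ha-1 y-1", "n ha-1 y-1", "kg ha-1 y-1",
                  "n y-1", "n y-1", "n y-1"),
    stringsAsFactors = FALSE
  )
}

#' Landscape indicator registry
#'
#' Names (and order) of the eight per-unit landscape indicators:
#' water/total, land/total, saltmarsh/total area ratios, the
#' freshwater/brackish and land/saltmarsh ratios, saltmarsh
#' perimeter/area in km per km2, and landscape Shannon diversity and
#' evenness.
#'
#' @return Character vector of the eight indicator column names.
#' @export
landscape_indicator_names <- function() {
  c("water_total", "land_total", "saltmarsh_total",
    "freshwater_brackish", "land_saltmarsh",
    "saltmarsh_perimeter_area", "shannon_diversity", "shannon_evenness")
}

# numeric record fields carried for every unit-year
record_fields <- function() {
  c("fry_sown", "fish_catch", "waterbirds_censused", "waterfowl_catch",
    "salicornia_harvest", "honey_harvest",
    "tourists", "excursionists", "birdwatchers")
}
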