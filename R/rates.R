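#' Default literature-style rate table
#'
#' Bundles the per-habitat process rates used by the capacity
#' indicators. The study system's rates come from field literature on
#' Mediterranean transitional waters and are not settled constants;
#' these defaults are representative magnitudes and every entry is
#' overridable.
#'
#' \itemize{
#'   \item `carbon`: net carbon sequestration (gC m-2 y-1) for common
#'     reed stands, vegetated (accreting) saltmarsh, and seagrass
#'     meadows.
#'   \item `seagrass_epiphyte_increment`: additional carbon deposition
#'     by microcalcareous epiphytes on seagrass leaves (gC m-2 y-1).
#'   \item `nitrogen_load`: areal nitrogen load on brackish basins
#'     (gN m-2 y-1).
#'   \item `removal_fraction_default`: fallback denitrification removal
#'     fraction when a unit-specific value is not supplied.
#'   \item `salicornia_biomass`: harvestable Salicornia biomass
#'     (kg m-2 y-1).
#'   \item `honey_yield`: honey obtainable per unit area of flowering
#'     sea lavender (g m-2 y-1).
#' }
#'
#' @return Named list of class `rate_table`.
#' @export
default_rate_table <- function() {
  structure(list(
    carbon = c(reed_stand = 600, vegetated_saltmarsh = 200,
               seagrass_meadow = 150),
    seagrass_epiphyte_increment = 30,
    nitrogen_load = 25,
    removal_fraction_default = 0.45,
    salicornia_biomass = 0.3,
    honey_yield = 2
  ), class = c("rate_table", "list"))
}

#' Default attractiveness weight sets
#'
#' Factor weights for the four map-algebra attractiveness indices.
#' The survey-derived weights of the study system are not public;
#' these are documented placeholders, normalised to sum to 1 within
#' each index, and fully overridable.
#'
#' @return Named list with elements `lifecycle`, `tourism`,
#'   `cognitive`, `birdwatching`, each a named numeric weight vector
#'   over that index's factor layers.
#' @export
default_attractiveness_weights <- function() {
  list(
    lifecycle = c(saltmarsh = 0.20, freshwater = 0.20, shrub = 0.10,
                  herbaceous = 0.10, fish_suitability = 0.40),
    tourism = c(saltmarsh = 0.30, fauna = 0.30, water_quality = 0.25,
                terrestrial_proximity = 0.15),
    cognitive = c(saltmarsh = 0.25, fauna = 0.25, water_quality = 0.20,
                  terrestrial_proximity = 0.10, accessibility = 0.20),
    birdwatching = c(paths = 0.20, saltmarsh = 0.25, nesting = 0.25,
                     bird_probability = 0.30)
  )
}
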