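# The nine ecosystem-service capacity/flow indicators.

#' Climate regulation: carbon sequestration
#'
#' Total annual carbon sequestration from reed stands, vegetated
#' saltmarsh accretion and seagrass meadows (the seagrass rate is
#' incremented by the epiphytic carbon-deposition term), expressed as a
#' unit mean in gC m-2 y-1. Capacity and flow are equivalent for this
#' service: sequestration happens where the habitat is.
#'
#' @param habitats Named list of logical matrices with at least
#'   `reed_stand`, `vegetated_saltmarsh`, `seagrass_meadow`.
#' @param rates A [default_rate_table()].
#' @param pixel_size Pixel edge (m).
#' @param unit_area Unit area in m2 (non-nodata extent).
#' @return List with `capacity`, `flow` (gC m-2 y-1, identical) and
#'   `total_gC` (gC y-1).
#' @export
climate_regulation <- function(habitats, rates, pixel_size, unit_area) {
  need <- c("reed_stand", "vegetated_saltmarsh", "seagrass_meadow")
  px2 <- pixel_size^2
  total <- 0
  for (h in need) {
    area <- sum(habitats[[h]]) * px2
    if (area == 0) next
    rate <- rates$carbon[[h]]
    if (is.null(rate) || is.na(rate)) {
      stop("no carbon rate defined for present habitat: ", h)
    }
    if (h == "seagrass_meadow") {
      rate <- rate + rates$seagrass_epiphyte_increment
    }
    total <- total + area * rate
  }
  mean_rate <- total / unit_area
  list(capacity = mean_rate, flow = mean_rate, total_gC = total)
}

#' Water purification: nitrogen removal by denitrification
#'
#' Capacity and flow are the percentage of the areal nitrogen load
#' removed in the brackish basins; the removed mass is reported
#' alongside.
#'
#' @param brackish_area Brackish water area (m2).
#' @param n_load Areal nitrogen load (gN m-2 y-1), >= 0.
#' @param removal_fraction Fraction removed, in \[0, 1\].
#' @return List with `capacity`, `flow` (percent, identical) and
#'   `removed_gN` (gN y-1).
#' @export
water_purification <- function(brackish_area, n_load, removal_fraction) {
  if (n_load < 0) stop("nitrogen load must be non-negative")
  if (removal_fraction < 0 || removal_fraction > 1) {
    stop("removal fraction must lie in [0, 1]")
  }
  pct <- removal_fraction * 100
  list(capacity = pct, flow = pct,
       removed_gN = removal_fraction * n_load * brackish_area)
}

#' Map-algebra attractiveness index
#'
#' Weighted per-pixel sum of factor layers, rescaled so that the
#' minimum over the whole unit set maps to 0 and the maximum to 1.
#' Layers may be logical (presence) or continuous; pixels outside a
#' unit (`inside` FALSE) are excluded from the rescaling and returned
#' as NA. With a single unit the rescaling is over that unit alone.
#' A constant raw index (e.g. all layers zero) maps to all zeros.
#'
#' @param factor_layers For one unit: a list of congruent matrices.
#'   For a unit set: a list of such lists (one per unit).
#' @param weights Non-negative weights, one per factor layer.
#' @param inside Optional logical matrix (or list of them) marking
#'   pixels inside the unit.
#' @return For one unit: list with `index` (matrix in \[0,1\]) and
#'   `mean`. For a unit set: list with `index` (list of matrices) and
#'   `mean` (named numeric vector).
#' @export
attractiveness_index <- function(factor_layers, weights, inside = NULL) {
  single <- all(vapply(factor_layers, is.matrix, logical(1)))
  units <- if (single) list(factor_layers) else factor_layers
  insides <- if (is.null(inside)) NULL else if (single) list(inside) else inside
  if (any(weights < 0)) stop("weights must be non-negative")
  raw <- vector("list", length(units))
  for (i in seq_along(units)) {
    layers <- units[[i]]
    if (length(layers) == 0) stop("at least one factor layer is required")
    if (length(weights) != length(layers)) {
      stop("got ", length(weights), " weights for ", length(layers),
           " factor layers")
    }
    dims <- vapply(layers, function(m) paste(dim(m), collapse = "x"),
                   character(1))
    if (length(unique(dims)) != 1) stop("factor layers are not congruent")
    acc <- matrix(0, nrow(layers[[1]]), ncol(layers[[1]]))
    for (j in seq_along(layers)) acc <- acc + weights[j] * layers[[j]]
    if (!is.null(insides)) acc[!insides[[i]]] <- NA_real_
    raw[[i]] <- acc
  }
  all_vals <- unlist(lapply(raw, function(m) m[!is.na(m)]))
  lo <- min(all_vals); hi <- max(all_vals)
  scaled <- lapply(raw, function(m) {
    if (hi > lo) (m - lo) / (hi - lo) else m * 0
  })
  means <- vapply(scaled, function(m) mean(m, na.rm = TRUE), numeric(1))
  if (single) list(index = scaled[[1]], mean = means[1])
  else list(index = scaled, mean = means)
}

#' Lifecycle-support flow
#'
#' Per unit, the across-years mean sown fry biomass and mean censused
#' migratory waterbirds are each min-max normalised across the unit
#' set and summed, giving a 0-2 combined flow.
#'
#' @param records data.frame of unit-year records for >= 2 units with
#'   columns `legend_id`, `fry_sown`, `waterbirds_censused`.
#' @return Named numeric vector (by legend_id) in \[0, 2\].
#' @export
lifecycle_flow <- function(records) {
  ids <- unique(records$legend_id)
  if (length(ids) < 2) {
    stop("lifecycle flow normalisation needs at least 2 units")
  }
  fry <- tapply(records$fry_sown, records$legend_id, mean, na.rm = TRUE)
  birds <- tapply(records$waterbirds_censused, records$legend_id, mean,
                  na.rm = TRUE)
  out <- minmax_normalize(as.numeric(fry)) +
    minmax_normalize(as.numeric(birds))
  names(out) <- names(fry)
  out
}

#' Mean yearly flow from management records
#'
#' Arithmetic mean of one record field over the years available in the
#' window; missing years are excluded, never zero-filled.
#'
#' @param records data.frame of unit-year records (one unit).
#' @param field Name of a numeric record field.
#' @param years_window Years to include (default: all years present).
#' @return Mean per-year value, or NA if no usable records fall in the
#'   window.
#' @export
record_mean_flow <- function(records, field,
                             years_window = unique(records$year)) {
  if (!field %in% names(records)) stop("unknown record field: ", field)
  x <- records[[field]][records$year %in% years_window]
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Huntable-waterbird density surface by inverse-distance weighting
#'
#' Exact IDW interpolation of census-point densities onto a raster
#' template. Coincident points with conflicting values are averaged
#' with a warning. A single point yields a constant surface.
#'
#' @param census_points data.frame with `row`, `col`, `value`
#'   (n ha-1 y-1).
#' @param raster_template An [lc_raster()] providing grid shape,
#'   pixel size and the nodata extent.
#' @param power IDW power (default 2).
#' @return List with `surface` (matrix, NA outside the unit) and
#'   `capacity` (surface mean over the unit).
#' @export
huntable_density_surface <- function(census_points, raster_template,
                                     power = 2) {
  if (nrow(census_points) < 1) stop("at least one census point is required")
  key <- paste(census_points$row, census_points$col)
  if (anyDuplicated(key)) {
    warning("coincident census points averaged")
    census_points <- aggregate(value ~ row + col, census_points, mean)
  }
  g <- raster_template$grid
  nr <- nrow(g); nc <- ncol(g)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  surf <- matrix(NA_real_, nr, nc)
  at_point <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(census_points))) {
    d2 <- (rows - census_points$row[i])^2 + (cols - census_points$col[i])^2
    d <- sqrt(d2) * raster_template$pixel_size
    w <- ifelse(d == 0, 0, d^(-power))
    num <- num + w * census_points$value[i]
    den <- den + w
    surf[census_points$row[i], census_points$col[i]] <-
      census_points$value[i]
    at_point[census_points$row[i], census_points$col[i]] <- TRUE
  }
  surf[!at_point] <- (num / den)[!at_point]
  if (nrow(census_points) == 1) surf[] <- census_points$value[1]
  surf[g == 0L] <- NA_real_
  list(surface = surf, capacity = mean(surf, na.rm = TRUE))
}

#' Wild-food capacity
#'
#' Harvestable Salicornia biomass plus sea-lavender honey (converted
#' g to kg), per unit hectare.
#'
#' @param salicornia_mask Logical matrix of detected Salicornia pixels.
#' @param limonium_area Area covered by flowering sea lavender (m2).
#' @param rates A [default_rate_table()].
#' @param pixel_size Pixel edge (m).
#' @param unit_area Unit area (m2).
#' @return List with `capacity` (kg ha-1 y-1) and the `salicornia_kg`
#'   and `honey_kg` components (kg y-1).
#' @export
wildfood_capacity <- function(salicornia_mask, limonium_area, rates,
                              pixel_size, unit_area) {
  sal_kg <- sum(salicornia_mask) * pixel_size^2 * rates$salicornia_biomass
  honey_kg <- limonium_area * rates$honey_yield / 1000
  list(capacity = (sal_kg + honey_kg) / (unit_area / 1e4),
       salicornia_kg = sal_kg, honey_kg = honey_kg)
}

#' Aquaculture capacity
#'
#' Mean of the potential fish-biomass density surface over the
#' brackish-water pixels.
#'
#' @param potential_density_surface Numeric matrix (kg ha-1 y-1).
#' @param brackish_mask Logical matrix, congruent with the surface.
#' @return Capacity in kg ha-1 y-1, or NA (flagged missing) when the
#'   unit has no brackish water.
#' @export
aquaculture_capacity <- function(potential_density_surface, brackish_mask) {
  if (!identical(dim(potential_density_surface), dim(brackish_mask))) {
    stop("surface and mask are not congruent")
  }
  if (!any(brackish_mask)) return(NA_real_)
  mean(potential_density_surface[brackish_mask])
}

# iterated 4-neighbour average of a 0/1 mask: soft proximity layer
proximity_layer <- function(mask, iters = 6) {
  f <- mask * 1
  for (i in seq_len(iters)) {
    f <- (f +
      shift_matrix(f, 1, 0, 0) + shift_matrix(f, -1, 0, 0) +
      shift_matrix(f, 0, 1, 0) + shift_matrix(f, 0, -1, 0)) / 5
  }
  if (max(f) > 0) f / max(f) else f
}

#' Assess the nine ecosystem services over a scenario
#'
#' Computes raw capacity and flow for every unit and service: carbon
#' sequestration, nitrogen removal, lifecycle-support attractiveness
#' and normalised fry+waterbird flow, aquaculture potential and catch,
#' huntable-waterbird IDW capacity and hunting-register catch,
#' NDVI-detected wild-food capacity and harvest, and the three
#' survey-weighted cultural attractiveness indices with their visitor
#' flows. Attractiveness indices are rescaled jointly over the unit
#' set.
#'
#' @param scenario A [generate_scenario()] object.
#' @param rates A [default_rate_table()].
#' @param weights A [default_attractiveness_weights()] list.
#' @return Long data.frame (unit x ES) with columns `legend_id`,
#'   `group`, `es`, `category`, `capacity`, `flow`, `capacity_unit`,
#'   `flow_unit`.
#' @export
assess_ecosystem_services <- function(scenario,
                                      rates = default_rate_table(),
                                      weights =
                                        default_attractiveness_weights()) {
  stopifnot(inherits(scenario, "valli_scenario"))
  reg <- es_registry()
  units <- scenario$units
  ps <- scenario$config$pixel_size
  all_records <- do.call(rbind, lapply(units, function(u) u$records))
  lc_flow <- lifecycle_flow(all_records)

  layer_sets <- list(lifecycle = list(), tourism = list(),
                     cognitive = list(), birdwatching = list())
  insides <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    g <- u$raster$grid
    m <- u$habitats$masks
    s <- u$habitats$surfaces
    inside <- g != 0L
    insides[[i]] <- inside
    land_prox <- proximity_layer(g == 1L | m$shrub | m$herbaceous)
    layer_sets$lifecycle[[i]] <- list(
      (g == 2L) * 1, (g == 4L) * 1, m$shrub * 1, m$herbaceous * 1,
      s$fish_suitability)
    layer_sets$tourism[[i]] <- list(
      (g == 2L) * 1, s$bird_probability, s$water_quality, land_prox)
    layer_sets$cognitive[[i]] <- list(
      (g == 2L) * 1, s$bird_probability, s$water_quality, land_prox,
      proximity_layer(m$pedestrian_path))
    layer_sets$birdwatching[[i]] <- list(
      m$pedestrian_path * 1, (g == 2L) * 1, m$nesting_area * 1,
      s$bird_probability)
  }
  attr_mean <- lapply(names(layer_sets), function(nm) {
    attractiveness_index(layer_sets[[nm]], weights[[nm]], insides)$mean
  })
  names(attr_mean) <- names(layer_sets)

  rows <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    g <- u$raster$grid
    m <- u$habitats$masks
    unit_area <- sum(g != 0L) * ps^2
    clim <- climate_regulation(m, rates, ps, unit_area)
    pur <- water_purification(class_area(u$raster, 3L),
                              rates$nitrogen_load,
                              u$latents$removal_fraction)
    idw <- huntable_density_surface(u$habitats$census_points, u$raster)
    ann <- mapply(ndvi, u$habitats$reflectance$red,
                  u$habitats$reflectance$nir, SIMPLIFY = FALSE)
    sal_mask <- detect_vegetation_patches(
      ann, scenario$config$ndvi_range) & (g == 2L)
    wf <- wildfood_capacity(sal_mask, u$habitats$limonium_area, rates,
                            ps, unit_area)
    cap <- c(
      climate_regulation = clim$capacity,
      water_purification = pur$capacity,
      lifecycle_support = attr_mean$lifecycle[i],
      aquaculture = aquaculture_capacity(
        u$habitats$surfaces$potential_biomass, g == 3L),
      hunting = idw$capacity,
      wild_food = wf$capacity,
      tourism = attr_mean$tourism[i],
      cognitive_development = attr_mean$cognitive[i],
      birdwatching = attr_mean$birdwatching[i])
    rmf <- function(f) record_mean_flow(u$records, f)
    flow <- c(
      climate_regulation = clim$flow,
      water_purification = pur$flow,
      lifecycle_support = unname(
        lc_flow[as.character(u$unit$legend_id)]),
      aquaculture = rmf("fish_catch"),
      hunting = rmf("waterfowl_catch"),
      wild_food = rmf("salicornia_harvest") + rmf("honey_harvest"),
      tourism = rmf("tourists"),
      cognitive_development = rmf("excursionists"),
      birdwatching = rmf("birdwatchers"))
    rows[[i]] <- data.frame(
      legend_id = u$unit$legend_id, group = u$unit$group, es = reg$es,
      category = reg$category, capacity = unname(cap[reg$es]),
      flow = unname(flow[reg$es]), capacity_unit = reg$capacity_unit,
      flow_unit = reg$flow_unit, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- out$es %in% c("lifecycle_support", "tourism",
                       "cognitive_development", "birdwatching") &
    (out$capacity < -1e-9 | out$capacity > 1 + 1e-9)
  if (any(bad, na.rm = TRUE)) {
    stop("attractiveness capacity outside [0, 1]")
  }
  out
}
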