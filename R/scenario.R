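# Synthetic study scenarios.
#
# The real management records and classified imagery behind the study
# system are private, so the package ships a seed-deterministic
# generator whose group-conditioned defaults encode the qualitative
# structure the analysis assumes: water-dominated F units, land-heavy R
# units, no freshwater pools in abandoned N units, ragged many-patch
# saltmarsh in M and H, no cultural flow in F and H, no provisioning
# records in N and R, and two designated M units whose fish catch
# exceeds their productive potential.

# deterministic substream seed, always < 2^31
derive_seed <- function(master, unit_id, stage) {
  v <- (as.double(master) %% 2147483647) * 48271 +
    as.double(unit_id) * 1299709 + as.double(stage) * 7919
  as.integer(v %% 2147483647)
}

# truncated normal on [0, Inf) by rejection (means used here are well
# above zero, so rejection is cheap); sd = cv * mean
rtrunc_pos <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) {
    k <- x < 0
    x[k] <- rnorm(sum(k), mean, sd)
  }
  x
}

#' Default synthetic-scenario configuration
#'
#' Per-group generator parameters: land-cover class proportion targets,
#' patch-count ranges and per-class edge roughness for the region
#' grower, habitat fractions, latent unit-level means (potential fish
#' density, huntable-bird density, waterbird census density,
#' denitrification fraction, water quality), and yearly management
#' record means. Two designated multiple-ES units (legend 25 and 26 by
#' default) are flagged `flow_exceeds_capacity`: their fish catch is
#' set above their potential density, which itself is drawn reduced.
#'
#' @param pixel_size Pixel edge in metres (default 25).
#' @param years Record years (default 2010:2020).
#' @return A nested list of class `scenario_config`.
#' @export
default_scenario_config <- function(pixel_size = 25, years = 2010:2020) {
  grp <- function(props, marsh_patches, roughness_marsh, hab, lat, rec) {
    list(class_props = props,
         n_patches = list(land = c(1, 3), saltmarsh = marsh_patches,
                          brackish = c(1, 2), freshwater = c(1, 2)),
         roughness = c(land = 0.2, saltmarsh = roughness_marsh,
                       brackish = 0.05, freshwater = 0.15),
         habitat_fractions = hab, latent = lat, record_means = rec)
  }
  cfg <- list(
    pixel_size = pixel_size,
    years = years,
    proportion_concentration = 300,
    proportion_tolerance = 0.08,
    footprint_fill = 0.62,
    record_cv = 0.2,
    ndvi_range = c(0.2, 0.4),
    ndvi_years = 3,
    flow_exceeds_capacity_units = c(25L, 26L),
    flow_exceeds_capacity_mult = 1.5,
    reduced_capacity_mult = 0.7,
    groups = list(
      F = grp(c(land = 0.08, saltmarsh = 0.10, brackish = 0.76,
                freshwater = 0.06),
              marsh_patches = c(1, 3), roughness_marsh = 0.12,
              hab = c(reed = 0.10, veg_marsh = 0.80, seagrass = 0.25,
                      shrub = 0.10, herb = 0.25, paths = 0.03,
                      nesting = 0.15, salicornia = 0.25, limonium = 0.20),
              lat = c(aqua_density = 160, bird_density = 1.5,
                      census_density = 2.5, removal_fraction = 0.50,
                      water_quality = 0.80),
              rec = c(fry_sown = 25, fish_catch_util = 0.50,
                      waterfowl_util = 0.15, salicornia_harvest = 15,
                      honey_harvest = 1, tourists = 0, excursionists = 0,
                      birdwatchers = 0)),
      M = grp(c(land = 0.14, saltmarsh = 0.12, brackish = 0.66,
                freshwater = 0.08),
              marsh_patches = c(6, 12), roughness_marsh = 0.65,
              hab = c(reed = 0.15, veg_marsh = 0.80, seagrass = 0.20,
                      shrub = 0.20, herb = 0.30, paths = 0.05,
                      nesting = 0.25, salicornia = 0.35, limonium = 0.25),
              lat = c(aqua_density = 140, bird_density = 2.5,
                      census_density = 3.5, removal_fraction = 0.48,
                      water_quality = 0.75),
              rec = c(fry_sown = 15, fish_catch_util = 0.45,
                      waterfowl_util = 0.35, salicornia_harvest = 25,
                      honey_harvest = 1.7, tourists = 300,
                      excursionists = 200, birdwatchers = 50)),
      H = grp(c(land = 0.15, saltmarsh = 0.12, brackish = 0.63,
                freshwater = 0.10),
              marsh_patches = c(6, 12), roughness_marsh = 0.65,
              hab = c(reed = 0.15, veg_marsh = 0.80, seagrass = 0.15,
                      shrub = 0.20, herb = 0.30, paths = 0.03,
                      nesting = 0.30, salicornia = 0.25, limonium = 0.20),
              lat = c(aqua_density = 120, bird_density = 3.0,
                      census_density = 4.0, removal_fraction = 0.46,
                      water_quality = 0.70),
              rec = c(fry_sown = 5, fish_catch_util = 0.20,
                      waterfowl_util = 0.50, salicornia_harvest = 18,
                      honey_harvest = 1.2, tourists = 0, excursionists = 0,
                      birdwatchers = 0)),
      R = grp(c(land = 0.55, saltmarsh = 0.08, brackish = 0.36,
                freshwater = 0.01),
              marsh_patches = c(1, 3), roughness_marsh = 0.12,
              hab = c(reed = 0.02, veg_marsh = 0.60, seagrass = 0.05,
                      shrub = 0.15, herb = 0.25, paths = 0.15,
                      nesting = 0.10, salicornia = 0.12, limonium = 0.15),
              lat = c(aqua_density = 60, bird_density = 0.8,
                      census_density = 2.0, removal_fraction = 0.35,
                      water_quality = 0.50),
              rec = c(fry_sown = 0, fish_catch_util = 0,
                      waterfowl_util = 0, salicornia_harvest = 0,
                      honey_harvest = 0, tourists = 3000,
                      excursionists = 2000, birdwatchers = 400)),
      N = grp(c(land = 0.17, saltmarsh = 0.11, brackish = 0.72,
                freshwater = 0.00),
              marsh_patches = c(1, 3), roughness_marsh = 0.12,
              hab = c(reed = 0.02, veg_marsh = 0.50, seagrass = 0.08,
                      shrub = 0.05, herb = 0.15, paths = 0.00,
                      nesting = 0.10, salicornia = 0.08, limonium = 0.10),
              lat = c(aqua_density = 45, bird_density = 1.2,
                      census_density = 1.8, removal_fraction = 0.30,
                      water_quality = 0.45),
              rec = c(fry_sown = 0, fish_catch_util = 0,
                      waterfowl_util = 0, salicornia_harvest = 0,
                      honey_harvest = 0, tourists = 0,
                      excursionists = 1500, birdwatchers = 300))
    )
  )
  class(cfg) <- c("scenario_config", "list")
  cfg
}

check_scenario_config <- function(config) {
  for (g in names(config$groups)) {
    p <- config$groups[[g]]$class_props
    if (any(p < 0) || any(p > 1) || sum(p) > 1 + 1e-9) {
      stop("infeasible class proportion targets for group ", g,
           " (must lie in [0,1] and sum to at most 1)")
    }
  }
  invisible(TRUE)
}

#' Per-unit latent parameters
#'
#' Draws the unit-level means that couple the raster surfaces to the
#' management records: potential fish density (kg/ha/y), huntable-bird
#' density, waterbird census density (n/ha/y), denitrification removal
#' fraction and a 0-1 water-quality level. Deterministic in
#' (unit, config, seed). Designated `flow_exceeds_capacity` units draw
#' a reduced potential fish density.
#'
#' @param unit One row of [build_study_fixture()].
#' @param config A [default_scenario_config()] list.
#' @param seed Master integer seed.
#' @return Named list of the five latent values.
#' @export
generate_unit_latents <- function(unit, config, seed) {
  gcfg <- config$groups[[unit$group]]
  g <- gcfg$latent
  out <- withr_seed(derive_seed(seed, unit$legend_id, 1L), {
    # Dirichlet draw around the group's class-proportion targets; drawn
    # here (not in the landscape stage) so the records can be coupled
    # to the unit's actual habitat endowment
    base <- gcfg$class_props
    conc <- config$proportion_concentration
    p <- vapply(base, function(m) {
      if (m <= 0) 0 else rgamma(1, shape = conc * m)
    }, numeric(1))
    p <- p / sum(p)
    list(
      class_props = p,
      aqua_density = rtrunc_pos(1, g[["aqua_density"]],
                                0.12 * g[["aqua_density"]]),
      bird_density = rtrunc_pos(1, g[["bird_density"]],
                                0.15 * g[["bird_density"]]),
      census_density = rtrunc_pos(1, g[["census_density"]],
                                  0.15 * g[["census_density"]]),
      removal_fraction = min(1, max(0, rnorm(1, g[["removal_fraction"]],
                                             0.02))),
      water_quality = min(1, max(0, rnorm(1, g[["water_quality"]], 0.05)))
    )
  })
  if (unit$legend_id %in% config$flow_exceeds_capacity_units) {
    out$aqua_density <- out$aqua_density * config$reduced_capacity_mult
  }
  out
}

# local seed scope: run expr under a fixed seed, restore RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate one unit's synthetic land-cover raster
#'
#' Seeded multi-class region growing inside an irregular unit footprint.
#' Class pixel quotas are Dirichlet-sampled around the group's target
#' proportions; a per-class edge-roughness parameter controls boundary
#' raggedness (high for saltmarsh in groups M and H); group N draws no
#' freshwater. Deterministic in (unit, config, seed).
#'
#' @inheritParams generate_unit_latents
#' @param latents Output of [generate_unit_latents()] (re-derived if
#'   missing); carries the unit's class-proportion draw.
#' @return An [lc_raster()] covering the unit (nodata outside the
#'   footprint).
#' @export
generate_landscape <- function(unit, config, seed,
                               latents = generate_unit_latents(unit, config,
                                                               seed)) {
  check_scenario_config(config)
  gcfg <- config$groups[[unit$group]]
  ps <- config$pixel_size
  npix <- max(16L, as.integer(round(unit$total_area / ps^2)))
  side <- as.integer(ceiling(sqrt(npix / config$footprint_fill)))
  p <- latents$class_props
  withr_seed(derive_seed(seed, unit$legend_id, 2L), {
    # irregular footprint grown from the canvas centre
    fp_all <- matrix(TRUE, side, side)
    ctr <- as.integer((side %/% 2) + (side %/% 2) * side)  # 0-based index
    fp <- cpp_grow_regions(fp_all, ctr, 1L, npix, 0.35)
    footprint <- fp == 1L
    cells <- which(footprint) - 1L
    pick_seeds <- function(class_name, quota) {
      rng <- gcfg$n_patches[[class_name]]
      ns <- if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      sample(cells, max(1L, min(as.integer(ns), as.integer(quota))))
    }
    # phase 1: land, brackish and freshwater fill the whole footprint
    # (quotas inflated by 1/(1 - marsh share), low roughness so pocket
    # filling stays marginal)
    p1 <- p[c("land", "brackish", "freshwater")]
    p1 <- p1 / sum(p1)
    quota1 <- floor(p1 * npix)
    rest <- npix - sum(quota1)
    if (rest > 0) {
      ord <- order(p1 * npix - quota1, decreasing = TRUE)
      quota1[ord[seq_len(rest)]] <- quota1[ord[seq_len(rest)]] + 1
    }
    rough1 <- unname(gcfg$roughness[names(p1)])
    attempt <- function() {
      seed_cells <- integer(0); seed_class <- integer(0)
      for (k in seq_along(p1)) {
        if (quota1[k] == 0) next
        sc <- pick_seeds(names(p1)[k], quota1[k])
        seed_cells <- c(seed_cells, sc)
        seed_class <- c(seed_class, rep(k, length(sc)))
      }
      base_grid <- cpp_grow_regions(footprint, as.integer(seed_cells),
                                    as.integer(seed_class),
                                    as.integer(quota1), as.numeric(rough1))
      # phase 2: saltmarsh patches grown on a clean canvas with an
      # exact quota (roughness sets their edge raggedness), overlaid
      grid <- base_grid
      grid[grid == 2L] <- 3L  # relabel phase-1 brackish to final code
      grid[base_grid == 3L] <- 4L
      marsh_quota <- as.integer(round(p[["saltmarsh"]] * npix))
      if (marsh_quota > 0) {
        msc <- pick_seeds("saltmarsh", marsh_quota)
        marsh <- cpp_grow_regions(footprint, as.integer(msc),
                                  rep(1L, length(msc)), marsh_quota,
                                  gcfg$roughness[["saltmarsh"]])
        grid[marsh == 1L] <- 2L
      }
      achieved <- vapply(1:4, function(k) sum(grid == k), numeric(1)) / npix
      list(grid = grid, off = max(abs(achieved - p)))
    }
    # an unlucky seed placement can strand a class behind another and
    # distort the composition; retry within the seeded stream, keeping
    # the best of a few attempts
    best <- attempt()
    tries <- 1
    while (best$off > config$proportion_tolerance && tries < 8) {
      cand <- attempt()
      if (cand$off < best$off) best <- cand
      tries <- tries + 1
    }
    if (best$off > config$proportion_tolerance) {
      warning(sprintf(
        "unit %d: class proportions deviate from targets by up to %.3f",
        unit$legend_id, best$off))
    }
    lc_raster(best$grid, pixel_size = ps)
  })
}

#' Generate habitat layers and auxiliary surfaces for one unit
#'
#' Derives the binary habitat masks (reed stands, vegetated saltmarsh,
#' seagrass meadows, shrubs, herbaceous vegetation, freshwater pools,
#' pedestrian paths, nesting areas, true Salicornia and Limonium
#' patches) as group-conditioned subsets of the land-cover classes,
#' plus the continuous input surfaces: fish-suitability and potential
#' fish-biomass fields (smooth random fields scaled by the unit
#' latents), a water-quality field, a bird-probability field, a
#' synthetic 2-band (red/NIR) annual reflectance stack for NDVI
#' filtering, and huntable-waterbird census points.
#'
#' @inheritParams generate_unit_latents
#' @param raster The unit's [lc_raster()].
#' @param latents Output of [generate_unit_latents()].
#' @return Named list: `masks` (list of logical matrices),
#'   `limonium_area` (m2), `surfaces` (list of numeric matrices),
#'   `reflectance` (list with `red`, `nir`: lists of yearly matrices),
#'   `census_points` (data.frame row, col, value).
#' @export
generate_habitats <- function(unit, raster, config, seed,
                              latents = generate_unit_latents(unit, config,
                                                              seed)) {
  hf <- config$groups[[unit$group]]$habitat_fractions
  g <- raster$grid
  withr_seed(derive_seed(seed, unit$legend_id, 3L), {
    subset_mask <- function(class_mask, fraction) {
      m <- matrix(FALSE, nrow(g), ncol(g))
      idx <- which(class_mask)
      if (length(idx) > 0 && fraction > 0) {
        k <- round(fraction * length(idx))
        if (k > 0) m[sample(idx, k)] <- TRUE
      }
      m
    }
    land <- g == 1L; marsh <- g == 2L; brack <- g == 3L; fresh <- g == 4L
    veg_marsh <- subset_mask(marsh, hf[["veg_marsh"]])
    salicornia <- subset_mask(veg_marsh, hf[["salicornia"]])
    limonium <- subset_mask(veg_marsh & !salicornia, hf[["limonium"]])
    masks <- list(
      reed_stand = subset_mask(land, hf[["reed"]]),
      vegetated_saltmarsh = veg_marsh,
      seagrass_meadow = subset_mask(brack, hf[["seagrass"]]),
      shrub = subset_mask(land, hf[["shrub"]]),
      herbaceous = subset_mask(land, hf[["herb"]]),
      freshwater_pool = fresh,
      pedestrian_path = subset_mask(land, hf[["paths"]]),
      nesting_area = subset_mask(marsh, hf[["nesting"]]),
      salicornia = salicornia,
      limonium = limonium
    )
    inside <- g != 0L
    surfaces <- list(
      fish_suitability = pnorm(smooth_field(nrow(g), ncol(g))) *
        latents$water_quality * inside,
      potential_biomass = pmax(0, latents$aqua_density *
        (1 + 0.25 * smooth_field(nrow(g), ncol(g)))) * inside,
      water_quality = pmin(1, pmax(0, latents$water_quality +
        0.08 * smooth_field(nrow(g), ncol(g)))) * inside,
      bird_probability = pnorm(smooth_field(nrow(g), ncol(g))) *
        (latents$census_density / 4) * inside
    )
    # annual red/NIR stack: per-pixel target mean NDVI by cover type,
    # yearly draws jittered around it
    target <- matrix(runif(length(g), -0.5, -0.2), nrow(g), ncol(g))
    target[land] <- runif(sum(land), 0.50, 0.70)
    target[marsh] <- runif(sum(marsh), 0.02, 0.15)
    target[veg_marsh] <- runif(sum(veg_marsh), 0.45, 0.60)
    target[salicornia] <- runif(sum(salicornia), 0.24, 0.36)
    red <- nir <- vector("list", config$ndvi_years)
    for (y in seq_len(config$ndvi_years)) {
      v <- pmin(0.95, pmax(-0.95,
        target + rnorm(length(g), 0, 0.02)))
      red[[y]] <- matrix(0.1, nrow(g), ncol(g))
      nir[[y]] <- red[[y]] * (1 + v) / (1 - v)
    }
    water <- which(brack | fresh)
    k <- max(4L, as.integer(round(length(water) / 800)))
    pts <- sample(water, min(k, length(water)))
    census_points <- data.frame(
      row = ((pts - 1) %% nrow(g)) + 1,
      col = ((pts - 1) %/% nrow(g)) + 1,
      value = rtrunc_pos(length(pts), latents$bird_density,
                         0.10 * latents$bird_density))
    list(masks = masks,
         limonium_area = sum(limonium) * raster$pixel_size^2,
         surfaces = surfaces, reflectance = list(red = red, nir = nir),
         census_points = census_points)
  })
}

# zero-mean smooth random field, unit-ish variance, by iterated
# 4-neighbour averaging of white noise
smooth_field <- function(nr, nc, iters = 8) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  for (i in seq_len(iters)) {
    f <- (f +
      shift_matrix(f, 1, 0, 0) + shift_matrix(f, -1, 0, 0) +
      shift_matrix(f, 0, 1, 0) + shift_matrix(f, 0, -1, 0)) / 5
  }
  s <- sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate yearly management records for one unit
#'
#' Truncated-normal draws around group-conditioned means, with
#' structural zeros where the study system has none: groups F and H
#' have no cultural flow (tourists, excursionists, birdwatchers all 0),
#' group N has no exploitation records, group R no provisioning
#' records. Fish catch and waterfowl catch are coupled to the unit's
#' latent potential densities; on the designated
#' `flow_exceeds_capacity` units the fish-catch mean is set above the
#' unit's potential density.
#'
#' @inheritParams generate_unit_latents
#' @param latents Output of [generate_unit_latents()] (re-derived if
#'   missing).
#' @return data.frame with columns `legend_id`, `year` and the nine
#'   record fields, one row per year.
#' @export
generate_records <- function(unit, config, seed,
                             latents = generate_unit_latents(unit, config,
                                                             seed)) {
  if (length(config$years) == 0) stop("years window is empty")
  rec <- config$groups[[unit$group]]$record_means
  cv <- config$record_cv
  ny <- length(config$years)
  fish_mult <- rec[["fish_catch_util"]]
  if (unit$legend_id %in% config$flow_exceeds_capacity_units) {
    fish_mult <- config$flow_exceeds_capacity_mult
  }
  # wild-food harvests scale with the unit's actual saltmarsh endowment
  # relative to the group target (you can only pick where marsh grows)
  marsh_ratio <- latents$class_props[["saltmarsh"]] /
    config$groups[[unit$group]]$class_props[["saltmarsh"]]
  means <- c(
    fry_sown = rec[["fry_sown"]],
    fish_catch = fish_mult * latents$aqua_density,
    waterbirds_censused = latents$census_density,
    waterfowl_catch = rec[["waterfowl_util"]] * latents$bird_density,
    salicornia_harvest = rec[["salicornia_harvest"]] * marsh_ratio,
    honey_harvest = rec[["honey_harvest"]] * marsh_ratio,
    tourists = rec[["tourists"]],
    excursionists = rec[["excursionists"]],
    birdwatchers = rec[["birdwatchers"]])
  withr_seed(derive_seed(seed, unit$legend_id, 6L), {
    out <- data.frame(legend_id = unit$legend_id, year = config$years)
    for (f in names(means)) {
      out[[f]] <- if (means[[f]] == 0) {
        rep(0, ny)  # structural zero, never sampled
      } else {
        rtrunc_pos(ny, means[[f]], cv * means[[f]])
      }
    }
    out
  })
}

#' Generate a full synthetic study scenario
#'
#' Builds the 31-unit fixture and, for every unit, the land-cover
#' raster, habitat layers, auxiliary surfaces and yearly records. Pure
#' function of (config, seed).
#'
#' @param config A [default_scenario_config()] list.
#' @param seed Master integer seed.
#' @param fixture Optionally a subset of [build_study_fixture()] rows
#'   (all 31 by default).
#' @return Object of class `valli_scenario`: list with `config`,
#'   `seed`, `fixture`, `units` (per-unit list of `raster`, `latents`,
#'   `habitats`, `records`).
#' @export
generate_scenario <- function(config = default_scenario_config(), seed = 1,
                              fixture = build_study_fixture()) {
  check_scenario_config(config)
  units <- vector("list", nrow(fixture))
  names(units) <- as.character(fixture$legend_id)
  for (i in seq_len(nrow(fixture))) {
    unit <- fixture[i, ]
    latents <- generate_unit_latents(unit, config, seed)
    raster <- generate_landscape(unit, config, seed, latents)
    habitats <- generate_habitats(unit, raster, config, seed, latents)
    records <- generate_records(unit, config, seed, latents)
    units[[i]] <- list(unit = unit, latents = latents, raster = raster,
                       habitats = habitats, records = records)
  }
  structure(list(config = config, seed = seed, fixture = fixture,
                 units = units),
            class = "valli_scenario")
}

#' @export
print.valli_scenario <- function(x, ...) {
  cat(sprintf("<valli_scenario> %d units, seed %d, %d record years\n",
              length(x$units), x$seed, length(x$config$years)))
  print(table(x$fixture$group))
  invisible(x)
}
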