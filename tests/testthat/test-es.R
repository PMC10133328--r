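rates <- default_rate_table()

test_that("carbon sequestration is linear in habitat area", {
  mk <- function(n) matrix(FALSE, 10, 10)
  empty <- list(reed_stand = mk(), vegetated_saltmarsh = mk(),
                seagrass_meadow = mk())
  expect_equal(climate_regulation(empty, rates, 25, 62500)$capacity, 0)

  # 10,000 m2 of one habitat at 100 gC/m2/y over 100,000 m2
  r2 <- rates; r2$carbon[["vegetated_saltmarsh"]] <- 100
  hab <- empty
  hab$vegetated_saltmarsh <- matrix(FALSE, 20, 20)
  hab$vegetated_saltmarsh[1:4, 1:4] <- TRUE   # 16 px * 625 = 10,000 m2
  out <- climate_regulation(hab, r2, 25, 1e5)
  expect_equal(out$total_gC, 1e6)
  expect_equal(out$capacity, 10)
  expect_identical(out$capacity, out$flow)

  # mixed layers match a per-pixel multiply-accumulate oracle
  set.seed(91)
  hab <- list(reed_stand = matrix(runif(400) < 0.2, 20, 20),
              vegetated_saltmarsh = matrix(runif(400) < 0.3, 20, 20),
              seagrass_meadow = matrix(runif(400) < 0.25, 20, 20))
  out <- climate_regulation(hab, rates, 25, 20 * 20 * 625)
  oracle <- 625 * (sum(hab$reed_stand) * rates$carbon[["reed_stand"]] +
    sum(hab$vegetated_saltmarsh) * rates$carbon[["vegetated_saltmarsh"]] +
    sum(hab$seagrass_meadow) * (rates$carbon[["seagrass_meadow"]] +
                                rates$seagrass_epiphyte_increment))
  expect_equal(out$total_gC, oracle)

  # doubling every habitat area doubles the total (homogeneity)
  hab2 <- lapply(hab, function(m) rbind(m, m))
  out2 <- climate_regulation(hab2, rates, 25, 2 * 20 * 20 * 625)
  expect_equal(out2$total_gC, 2 * out$total_gC)

  bad <- rates; bad$carbon[["reed_stand"]] <- NA
  expect_error(climate_regulation(hab, bad, 25, 1e5), "reed_stand")
})

test_that("nitrogen removal percentage and mass follow the fraction", {
  expect_equal(water_purification(1e4, 10, 0)$capacity, 0)
  out <- water_purification(1e4, 10, 0.5)
  expect_equal(out$capacity, 50)
  expect_identical(out$capacity, out$flow)
  expect_equal(out$removed_gN, 5e4)
  set.seed(101)
  for (i in 1:5) {
    a <- runif(1, 1e3, 1e6); l <- runif(1, 1, 50); f <- runif(1)
    expect_equal(water_purification(a, l, f)$removed_gN, f * l * a)
  }
  expect_error(water_purification(1e4, -1, 0.5), "non-negative")
  expect_error(water_purification(1e4, 10, 1.5), "\\[0, 1\\]")
})

test_that("attractiveness index rescales the weighted layer sum", {
  z <- matrix(0, 5, 5)
  expect_equal(attractiveness_index(list(z, z), c(1, 1))$index, z)

  set.seed(111)
  b <- matrix(runif(25) < 0.5, 5, 5)
  out <- attractiveness_index(list(b * 1), 1)
  expect_equal(out$index, b * 1)

  layers <- replicate(3, matrix(runif(25), 5, 5), simplify = FALSE)
  w <- c(0.5, 0.3, 0.2)
  out <- attractiveness_index(layers, w)
  raw <- w[1] * layers[[1]] + w[2] * layers[[2]] + w[3] * layers[[3]]
  expect_equal(out$index, (raw - min(raw)) / (max(raw) - min(raw)))
  expect_true(all(out$index >= 0 & out$index <= 1))
  expect_equal(out$mean, mean(out$index))

  # joint rescaling across a unit set: global extrema map to 0 and 1
  u2 <- list(list(layers[[1]]), list(layers[[2]] + 2))
  joint <- attractiveness_index(u2, 1)
  expect_equal(max(joint$index[[2]]), 1)
  expect_equal(min(joint$index[[1]]), 0)
  expect_lt(max(joint$index[[1]]), 1)

  expect_error(attractiveness_index(layers, c(1, 2)), "weights")
  expect_error(
    attractiveness_index(list(matrix(0, 2, 2), matrix(0, 3, 3)), c(1, 1)),
    "congruent")
})

test_that("lifecycle flow is the sum of two normalized components", {
  rec <- data.frame(
    legend_id = rep(1:5, each = 2),
    fry_sown = c(10, 10, 0, 0, 5, 5, 20, 20, 2, 2),
    waterbirds_censused = c(4, 4, 0, 0, 1, 1, 8, 8, 3, 3))
  lf <- lifecycle_flow(rec)
  expect_equal(unname(lf[["4"]]), 2)  # maximal in both components
  expect_equal(unname(lf[["2"]]), 0)  # minimal in both
  fry <- tapply(rec$fry_sown, rec$legend_id, mean)
  birds <- tapply(rec$waterbirds_censused, rec$legend_id, mean)
  oracle <- (fry - min(fry)) / diff(range(fry)) +
    (birds - min(birds)) / diff(range(birds))
  expect_equal(unname(lf), as.numeric(oracle))
  expect_error(lifecycle_flow(rec[rec$legend_id == 1, ]), "2 units")
})

test_that("record mean flows average available years only", {
  rec <- data.frame(legend_id = 1, year = 2010:2013,
                    fish_catch = c(10, 20, NA, 30))
  expect_equal(record_mean_flow(rec, "fish_catch"), 20)
  expect_equal(record_mean_flow(rec, "fish_catch", 2010:2011), 15)
  rec$fish_catch <- rep(7, 4)
  expect_equal(record_mean_flow(rec, "fish_catch"), 7)
  set.seed(121)
  x <- runif(8, 0, 100)
  rec <- data.frame(legend_id = 1, year = 2010:2017, fish_catch = x)
  expect_equal(record_mean_flow(rec, "fish_catch"), sum(x) / 8)
  expect_true(is.na(record_mean_flow(rec, "fish_catch", 1999)))
  expect_error(record_mean_flow(rec, "nope"), "unknown record field")
})

test_that("IDW surface interpolates census points exactly", {
  tpl <- lc_raster(matrix(3L, 20, 20), pixel_size = 25)
  one <- data.frame(row = 5, col = 7, value = 2.5)
  out <- huntable_density_surface(one, tpl)
  expect_true(all(out$surface == 2.5))
  expect_equal(out$capacity, 2.5)

  set.seed(131)
  pts <- data.frame(row = c(2, 18, 9, 14), col = c(3, 16, 10, 2),
                    value = runif(4, 0.5, 4))
  out <- huntable_density_surface(pts, tpl, power = 2)
  for (i in 1:4) {
    expect_equal(out$surface[pts$row[i], pts$col[i]], pts$value[i])
  }
  # direct IDW formula oracle at a few off-point pixels
  for (px in list(c(1, 1), c(10, 15), c(20, 20))) {
    d <- sqrt((pts$row - px[1])^2 + (pts$col - px[2])^2) * 25
    expect_equal(out$surface[px[1], px[2]],
                 sum(pts$value / d^2) / sum(1 / d^2))
  }
  dup <- rbind(pts, data.frame(row = 2, col = 3, value = 9))
  expect_warning(huntable_density_surface(dup, tpl), "coincident")
  expect_error(huntable_density_surface(pts[0, ], tpl), "census point")
})

test_that("wild-food and aquaculture capacities are masked means", {
  expect_equal(
    wildfood_capacity(matrix(FALSE, 4, 4), 0, rates, 25, 1e6)$capacity, 0)
  mask <- matrix(FALSE, 20, 20); mask[1:4, 1:4] <- TRUE  # 10,000 m2
  r2 <- rates; r2$salicornia_biomass <- 0.2; r2$honey_yield <- 0
  out <- wildfood_capacity(mask, 0, r2, 25, 1e6)  # unit = 100 ha
  expect_equal(out$capacity, 20)
  out <- wildfood_capacity(mask, 5000, rates, 25, 1e6)
  expect_equal(out$capacity,
               (1e4 * rates$salicornia_biomass +
                  5000 * rates$honey_yield / 1000) / 100)

  surf <- matrix(runif(100, 50, 150), 10, 10)
  bm <- matrix(runif(100) < 0.4, 10, 10)
  expect_equal(aquaculture_capacity(surf, bm), mean(surf[bm]))
  expect_equal(aquaculture_capacity(surf * 0 + 3, bm), 3)
  surf2 <- surf; surf2[bm] <- 0
  expect_equal(aquaculture_capacity(surf2, bm), 0)
  expect_true(is.na(aquaculture_capacity(surf, bm & FALSE)))
  expect_error(aquaculture_capacity(surf, matrix(TRUE, 2, 2)), "congruent")
})

test_that("full assessment carries categories, units and ranges", {
  cfg <- default_scenario_config()
  sc <- suppressWarnings(
    generate_scenario(cfg, seed = 5, fixture = small_fixture(40)))
  es <- assess_ecosystem_services(sc)
  expect_equal(nrow(es), 31 * 9)
  expect_setequal(unique(es$es), es_registry()$es)
  expect_equal(unname(table(es$category)[c("regulating", "provisioning",
                                           "cultural")]),
               rep(31 * 3, 3), ignore_attr = TRUE)
  # capacity == flow identically for the two equivalent services
  for (e in c("climate_regulation", "water_purification")) {
    sub <- es[es$es == e, ]
    expect_identical(sub$capacity, sub$flow)
  }
  attrib <- es[es$es %in% c("lifecycle_support", "tourism",
                            "cognitive_development", "birdwatching"), ]
  expect_true(all(attrib$capacity >= 0 & attrib$capacity <= 1))
  expect_true(all(es$flow >= 0, na.rm = TRUE))
})
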