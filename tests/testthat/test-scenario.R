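test_that("generation is a pure function of (unit, config, seed)", {
  cfg <- default_scenario_config()
  u <- small_unit("M")
  r1 <- generate_landscape(u, cfg, 42)
  r2 <- generate_landscape(u, cfg, 42)
  expect_identical(r1$grid, r2$grid)
  expect_false(identical(r1$grid, generate_landscape(u, cfg, 43)$grid))
  rec1 <- generate_records(u, cfg, 42)
  rec2 <- generate_records(u, cfg, 42)
  expect_identical(rec1, rec2)
})

test_that("group-conditioned landscape structure holds", {
  cfg <- default_scenario_config()
  f <- generate_landscape(small_unit("F", 200), cfg, 7)
  tot <- sum(f$grid != 0)
  water <- sum(f$grid %in% c(3L, 4L)) / tot
  expect_gte(water, 0.7)
  expect_lte(water, 0.95)

  n <- generate_landscape(small_unit("N", 200), cfg, 7)
  expect_equal(sum(n$grid == 4L), 0)

  # infeasible proportion targets are rejected
  bad <- cfg
  bad$groups$F$class_props <- c(land = 0.5, saltmarsh = 0.5,
                                brackish = 0.5, freshwater = 0.1)
  expect_error(generate_landscape(small_unit("F"), bad, 1), "infeasible")
})

test_that("record structure encodes the management strategies", {
  cfg <- default_scenario_config()
  recF <- generate_records(small_unit("F"), cfg, 3)
  expect_true(all(recF$tourists == 0))
  expect_true(all(recF$excursionists == 0))
  expect_true(all(recF$birdwatchers == 0))
  expect_true(all(recF$fish_catch > 0))

  recH <- generate_records(small_unit("H"), cfg, 3)
  expect_true(all(recH$tourists == 0))

  recN <- generate_records(small_unit("N"), cfg, 3)
  expect_true(all(recN$fish_catch == 0))
  expect_true(all(recN$fry_sown == 0))
  expect_true(all(recN$waterfowl_catch == 0))

  recR <- generate_records(small_unit("R"), cfg, 3)
  expect_true(all(recR$tourists > 0))
  expect_equal(recR$year, 2010:2020)

  # designated flow-exceeds-capacity units catch above their potential
  fx <- build_study_fixture()
  for (id in cfg$flow_exceeds_capacity_units) {
    u <- fx[fx$legend_id == id, ]
    lat <- generate_unit_latents(u, cfg, 3)
    rec <- generate_records(u, cfg, 3, lat)
    expect_gt(mean(rec$fish_catch), lat$aqua_density)
  }

  empty <- cfg
  empty$years <- integer(0)
  expect_error(generate_records(small_unit("F"), empty, 1), "empty")
})

test_that("water/total group ordering F > {M,H,N} > R recurs across seeds", {
  cfg <- default_scenario_config()
  fx <- small_fixture(50)
  hit <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    wt <- vapply(seq_len(nrow(fx)), function(i) {
      r <- suppressWarnings(generate_landscape(fx[i, ], cfg, s))
      sum(r$grid %in% c(3L, 4L)) / sum(r$grid != 0L)
    }, numeric(1))
    m <- tapply(wt, fx$group, mean)
    if (m[["F"]] == max(m) && m[["R"]] == min(m)) hit <- hit + 1
  }
  expect_gte(hit / n_seeds, 0.9)
})

test_that("habitat layers are congruent subsets of their classes", {
  cfg <- default_scenario_config()
  u <- small_unit("M")
  lat <- generate_unit_latents(u, cfg, 5)
  r <- generate_landscape(u, cfg, 5, lat)
  hab <- generate_habitats(u, r, cfg, 5, lat)
  marsh <- r$grid == 2L
  expect_true(all(marsh[hab$masks$vegetated_saltmarsh]))
  expect_true(all(marsh[hab$masks$salicornia]))
  expect_true(all(marsh[hab$masks$nesting_area]))
  expect_true(all((r$grid == 3L)[hab$masks$seagrass_meadow]))
  expect_identical(dim(hab$surfaces$fish_suitability), dim(r$grid))
  expect_equal(length(hab$reflectance$red), cfg$ndvi_years)
  # salicornia pixels sit inside the configured NDVI detection window
  ann <- mapply(ndvi, hab$reflectance$red, hab$reflectance$nir,
                SIMPLIFY = FALSE)
  mean_ndvi <- Reduce(`+`, ann) / length(ann)
  sal <- hab$masks$salicornia
  if (any(sal)) {
    expect_gt(mean(mean_ndvi[sal] >= cfg$ndvi_range[1] &
                     mean_ndvi[sal] <= cfg$ndvi_range[2]), 0.95)
  }
})

test_that("scenario configs survive the YAML round trip", {
  cfg <- default_scenario_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  u <- small_unit("H")
  expect_identical(generate_landscape(u, cfg, 9)$grid,
                   generate_landscape(u, cfg2, 9)$grid)
  expect_identical(generate_records(u, cfg, 9),
                   generate_records(u, cfg2, 9))
})
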