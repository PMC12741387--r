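# Synthetic-world generator: tessellation, achieved truth, determinism.

test_that("ecoregion grid tiles the world rectangle without overlap", {
  eco <- makeEcoregions(2, 3, 5, origin = c(0, 0))
  expect_s4_class(eco, "EcoregionSet")
  expect_length(eco, 6L)
  areas <- featureAreas(eco)
  expect_equal(areas, rep(25, 6))
  all_rects <- do.call(rbind, geometry(eco))
  # union area equals sum of areas: pairwise disjoint interiors
  expect_equal(ecofactor:::.rectUnionArea(all_rects), sum(areas))
  # union is the 15 x 10 world rectangle
  expect_equal(range(all_rects[, c(1, 3)]), c(0, 15))
  expect_equal(range(all_rects[, c(2, 4)]), c(0, 10))
  expect_false(anyDuplicated(featureData(eco)$eco_id) > 0)
})

test_that("single-cell grid and out-of-bounds grids behave per contract", {
  one <- makeEcoregions(1, 1, 10, origin = c(0, 0))
  expect_length(one, 1L)
  expect_equal(featureAreas(one), 100)
  expect_error(makeEcoregions(2, 3, 80, origin = c(0, 0)), "bounds")
  expect_error(makeEcoregions(1, 1, 10, origin = c(175, 0)), "bounds")
})

test_that("regeneration with the same seed is identical", {
  a <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 6, seed = 5)
  b <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 6, seed = 5)
  expect_identical(rasterValues(a@landcover), rasterValues(b@landcover))
  expect_identical(rasterValues(a@richness), rasterValues(b@richness))
  expect_identical(geometry(countries(a)), geometry(countries(b)))
  expect_identical(worldTruth(a), worldTruth(b))
  c <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 6, seed = 6)
  expect_false(identical(rasterValues(a@landcover),
                         rasterValues(c@landcover)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulateWorld(2, 2, n_countries = 2, pixels_per_cell = 4,
                          seed = 3))
  expect_identical(runif(1), before)
})

test_that("countries partition the world and straddle ecoregions", {
  eco <- makeEcoregions(2, 3, 5)
  one <- makeCountries(eco, 1)
  expect_equal(featureAreas(one), 150)
  two <- makeCountries(eco, 2, seed = 1)
  # area conservation: country areas sum to the world area
  expect_equal(sum(featureAreas(two)), 150, tolerance = 1e-12)
  # per-ecoregion: intersections with all countries sum to ecoregion area
  w <- intersectionWeights(eco, two)
  per_eco <- tapply(w$area, w$eco_id, sum)
  expect_equal(as.numeric(per_eco), featureAreas(eco), tolerance = 1e-9)
  # interior boundary is offset from grid lines: some country covers >= 2
  # ecoregions partially
  expect_gt(nrow(w), 6L)
})

test_that("country-ecoregion intersection areas match rectangle arithmetic", {
  eco <- makeEcoregions(1, 2, 10, origin = c(0, 0))  # cells [0,10] and [10,20]
  cty <- rectLayer(list(matrix(c(5, 0, 15, 10), 1)),
                   data.frame(country = "X", iso_cc = "XX"),
                   class = "CountrySet")
  w <- intersectionWeights(eco, cty)
  # hand-computed overlaps: 5 x 10 with each cell
  expect_equal(sort(w$area), c(50, 50))
})

test_that("landcover achieves the nearest representable class share", {
  tw <- makeTestWorld(pixels_per_cell = 10L)
  ach <- tw$lc$achieved
  expect_equal(unname(ach[c("1", "2", "3")]), c(1, 0, 0.5))
  # all achieved values within half a pixel count of target
  expect_true(all(abs(ach - tw$sgf) <= 0.5 / 100))
  v <- rasterValues(tw$lc$raster)
  expect_true(all(v %in% c(0, 1, 2)))
  # direct pixel count for the 0.5 region equals 50 of 100
  eco3 <- geometry(tw$eco)[[3]]
  idx <- ecofactor:::.cellsInFeature(tw$lc$raster, eco3)
  expect_equal(sum(v[idx] %in% c(1, 2)), 50L)
})

test_that("coverage layers have exact area shares by construction", {
  tw <- makeTestWorld()
  expect_identical(unname(tw$wet$achieved), unname(tw$sw))
  # share 0 emits no polygon
  expect_false(1 %in% featureData(tw$wet$layer)$eco_id)
  # share 1 reproduces the ecoregion rectangle
  full <- geometry(tw$wet$layer)[[which(featureData(tw$wet$layer)$eco_id == 2)]]
  expect_equal(unname(full), unname(geometry(tw$eco)[[2]]))
  # 0.25 share on a 10x10 cell is a 5x5 rectangle
  q <- geometry(tw$wet$layer)[[which(featureData(tw$wet$layer)$eco_id == 3)]]
  expect_equal(unname(q[1, 3] - q[1, 1]), 5)
  expect_equal(unname(q[1, 4] - q[1, 2]), 5)
})

test_that("gep rasters are constant per region with composite = taxon sum", {
  tw <- makeTestWorld()
  expect_equal(unname(tw$gep$achieved),
               unname(rowSums(tw$gep_target)))
  expect_equal(unname(tw$gep$achieved[2]), 1.0)  # 0.1+0.2+0.3+0.4
  expect_equal(unname(tw$gep$achieved[1]), 0.0)
})

test_that("input validation rejects out-of-range targets", {
  eco <- makeEcoregions(1, 2, 10)
  expect_error(makeLandcover(eco, c(0.5, 1.2), 5), "\\[0, 1\\]")
  expect_error(makeCoverageLayer(eco, c(-0.1, 0.5), "wetland"), "\\[0, 1\\]")
  expect_error(makeGep(eco, matrix(c(-1, 0, 0, 0, 0, 0, 0, 0), 2, 4), 5),
               "non-negative")
})
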