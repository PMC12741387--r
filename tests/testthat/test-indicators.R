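# Indicator extraction: zonal class shares, overlay shares, composites.

test_that("classShare recovers painted shares exactly on aligned grids", {
  tw <- makeTestWorld(pixels_per_cell = 10L)
  got <- classShare(tw$lc$raster, c(1, 2), tw$eco)
  expect_equal(unname(got), unname(tw$lc$achieved))
})

test_that("classShare handles degenerate and error cases", {
  tw <- makeTestWorld()
  # region outside the raster extent has no covering pixels -> missing
  far <- makeEcoregions(1, 1, 5, origin = c(100, 0))
  expect_true(is.na(classShare(tw$lc$raster, c(1, 2), far)))
  expect_error(classShare(tw$lc$raster, integer(0), tw$eco), "non-empty")
  other_crs <- rectLayer(geometry(tw$eco), featureData(tw$eco),
                         crs = "EPSG:3857", class = "EcoregionSet")
  expect_error(classShare(tw$lc$raster, c(1, 2), other_crs), "CRS mismatch")
})

test_that("overlayShare recovers exact rectangle shares", {
  tw <- makeTestWorld()
  got <- overlayShare(tw$wet$layer, tw$eco)
  expect_equal(unname(got), unname(tw$sw), tolerance = 1e-12)
  sra <- overlayShare(tw$rdl$layer, tw$eco)
  expect_equal(unname(sra), unname(tw$sra), tolerance = 1e-12)
})

test_that("overlapping cover polygons are dissolved, not double-counted", {
  eco <- makeEcoregions(1, 1, 10)
  half <- matrix(c(0, 0, 5, 10), 1)
  cover <- rectLayer(list(half, half),
                     data.frame(id = 1:2))
  expect_equal(unname(overlayShare(cover, eco)), 0.5)
  # cover identical to the region gives exactly 1
  whole <- rectLayer(list(matrix(c(0, 0, 10, 10), 1)), data.frame(id = 1))
  expect_equal(unname(overlayShare(whole, eco)), 1)
  # empty cover layer gives 0
  none <- rectLayer(list(), data.frame(id = integer(0)))
  expect_equal(unname(overlayShare(none, eco)), 0)
})

test_that("gepComposite sums zonal means and respects the retention rule", {
  tw <- makeTestWorld()
  got <- gepComposite(tw$gep$rasters, tw$eco)
  expect_equal(unname(got), unname(tw$gep$achieved), tolerance = 1e-12)
  # poke a hole: one taxon all-NA within region 1 -> region 1 missing
  g2 <- tw$gep$rasters
  ras <- g2$birds
  idx <- ecofactor:::.cellsInFeature(ras, geometry(tw$eco)[[1]])
  v <- rasterValues(ras); v[idx] <- NA
  g2$birds <- gridRaster(v, ras@xmin, ras@ymax, ras@xres, ras@yres,
                         crsName(ras))
  got2 <- gepComposite(g2, tw$eco)
  expect_true(is.na(got2[["1"]]))
  expect_equal(got2[-1], got[-1])
  # mis-registered grids are refused
  bad <- g2
  bad$mammals <- gridRaster(rasterValues(g2$mammals), ras@xmin + 1,
                            ras@ymax, ras@xres, ras@yres, crsName(ras))
  expect_error(gepComposite(bad, tw$eco), "co-registered")
})

test_that("assembleIndicators flags validity per the retention rule", {
  tw <- makeTestWorld()
  tab <- assembleIndicators(tw$eco, tw$lc$raster, tw$wet$layer,
                            tw$rdl$layer, tw$gep$rasters)
  expect_true(all(tab$valid))
  expect_equal(tab$sgf_raw, unname(tw$lc$achieved))
  expect_true(all(tab$sw_raw >= 0 & tab$sw_raw <= 1))
  # knock out one region's gep -> that row invalid, others untouched
  g2 <- tw$gep$rasters
  ras <- g2$amphibians
  idx <- ecofactor:::.cellsInFeature(ras, geometry(tw$eco)[[4]])
  v <- rasterValues(ras); v[idx] <- NA
  g2$amphibians <- gridRaster(v, ras@xmin, ras@ymax, ras@xres, ras@yres,
                              crsName(ras))
  tab2 <- assembleIndicators(tw$eco, tw$lc$raster, tw$wet$layer,
                             tw$rdl$layer, g2)
  expect_false(tab2$valid[4])
  expect_true(all(tab2$valid[-4]))
  # empty region set -> empty table with full schema
  empty <- rectLayer(list(), data.frame(eco_id = integer(0),
                                        eco_name = character(0),
                                        biome_name = character(0)),
                     class = "EcoregionSet")
  tab0 <- assembleIndicators(empty, tw$lc$raster, tw$wet$layer,
                             tw$rdl$layer, tw$gep$rasters)
  expect_equal(nrow(tab0), 0L)
  expect_named(tab0, c("eco_id", "sgf_raw", "sw_raw", "gep_raw",
                       "sra_raw", "valid"))
})

test_that("per-region values are invariant to feature order", {
  tw <- makeTestWorld()
  perm <- c(4, 2, 6, 1, 3, 5)
  eco_p <- rectLayer(geometry(tw$eco)[perm],
                     featureData(tw$eco)[perm, ], class = "EcoregionSet")
  a <- assembleIndicators(tw$eco, tw$lc$raster, tw$wet$layer,
                          tw$rdl$layer, tw$gep$rasters)
  b <- assembleIndicators(eco_p, tw$lc$raster, tw$wet$layer,
                          tw$rdl$layer, tw$gep$rasters)
  b_sorted <- b[order(b$eco_id), ]
  rownames(b_sorted) <- NULL
  expect_equal(b_sorted, a)
})

test_that("recovered indicators match stored truth on a simulated world", {
  w <- simulateWorld(5, 5, n_countries = 3, pixels_per_cell = 8, seed = 21)
  tab <- assembleIndicators(ecoregions(w), w@landcover, w@wetlands,
                            w@roadless, w@gep)
  tr <- worldTruth(w)
  expect_equal(tab$sgf_raw, tr$sgf_true)                       # exact paint
  expect_equal(tab$sw_raw, tr$sw_true, tolerance = 1e-9)
  expect_equal(tab$sra_raw, tr$sra_true, tolerance = 1e-9)
  expect_equal(tab$gep_raw, tr$gep_true, tolerance = 1e-12)    # constants
})
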