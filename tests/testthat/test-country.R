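# Area-weighted national aggregation.

test_that("intersection weights reproduce rectangle-overlap arithmetic", {
  eco <- makeEcoregions(1, 2, 10, origin = c(0, 0))
  # country equal to ecoregion 1: single weight, full area
  same <- rectLayer(list(matrix(c(0, 0, 10, 10), 1)),
                    data.frame(country = "A", iso_cc = "AA"),
                    class = "CountrySet")
  w <- intersectionWeights(eco, same)
  expect_equal(nrow(w), 1L)
  expect_equal(w$area, 100)
  # country straddling two equal half-cells: two equal weights
  strad <- rectLayer(list(matrix(c(5, 0, 15, 10), 1)),
                     data.frame(country = "B", iso_cc = "BB"),
                     class = "CountrySet")
  w2 <- intersectionWeights(eco, strad)
  expect_equal(w2$area, c(50, 50))
  # disjoint pair produces no entry
  far <- rectLayer(list(matrix(c(50, 50, 60, 60), 1)),
                   data.frame(country = "C", iso_cc = "CC"),
                   class = "CountrySet")
  expect_equal(nrow(intersectionWeights(eco, far)), 0L)
})

test_that("countryEF computes the area-weighted mean over retained regions", {
  cty <- rectLayer(list(matrix(c(0, 0, 1, 1), 1)),
                   data.frame(country = "X", iso_cc = "XX"),
                   class = "CountrySet")
  ef <- data.frame(eco_id = 1:2, eco_name = c("a", "b"),
                   biome_name = c("b1", "b2"),
                   ef_raw = c(0.2, 0.4), ef = c(2.0, 4.0))
  # worked example: areas 1:3 over EF 2 and 4 -> 3.5
  w <- data.frame(iso_cc = "XX", eco_id = 1:2, area = c(1, 3))
  got <- countryEF(w, ef, cty)
  expect_equal(got$ef, 3.5)
  # single ecoregion: the mean is that EF
  w1 <- data.frame(iso_cc = "XX", eco_id = 2, area = 7)
  expect_equal(countryEF(w1, ef, cty)$ef, 4.0)
  # equal areas over EF 1 and 3 -> 2
  ef2 <- ef; ef2$ef <- c(1, 3)
  weq <- data.frame(iso_cc = "XX", eco_id = 1:2, area = c(5, 5))
  expect_equal(countryEF(weq, ef2, cty)$ef, 2.0)
})

test_that("countries without retained ecoregion coverage are omitted", {
  cty <- rectLayer(list(matrix(c(0, 0, 1, 1), 1),
                        matrix(c(1, 0, 2, 1), 1)),
                   data.frame(country = c("X", "Y"),
                              iso_cc = c("XX", "YY")),
                   class = "CountrySet")
  ef <- data.frame(eco_id = 1, eco_name = "a", biome_name = "b",
                   ef_raw = 0.2, ef = 2.0)
  # country Y intersects only the non-retained ecoregion 99
  w <- data.frame(iso_cc = c("XX", "YY"), eco_id = c(1, 99),
                  area = c(1, 1))
  got <- countryEF(w, ef, cty)
  expect_equal(got$iso_cc, "XX")
  # the retained-only rule also drops region 99 from mixed countries
  w2 <- data.frame(iso_cc = c("XX", "XX"), eco_id = c(1, 99),
                   area = c(1, 100))
  expect_equal(countryEF(w2, ef, cty)$ef, 2.0)
})

test_that("country EF is convex and scale-equivariant", {
  w <- simulateWorld(4, 4, n_countries = 3, pixels_per_cell = 6, seed = 31)
  res <- suppressMessages(runWorldPipeline(w))
  wts <- intersectionWeights(ecoregions(w), countries(w))
  for (i in seq_len(nrow(res$country_table))) {
    iso <- res$country_table$iso_cc[i]
    ids <- wts$eco_id[wts$iso_cc == iso]
    efs <- res$ef_table$ef[res$ef_table$eco_id %in% ids]
    expect_gte(res$country_table$ef[i], min(efs) - 1e-12)
    expect_lte(res$country_table$ef[i], max(efs) + 1e-12)
  }
  # scale equivariance: multiplying ecoregion EFs by c scales country EFs by c
  ef_scaled <- res$ef_table
  ef_scaled$ef <- ef_scaled$ef * 3.7
  scaled <- countryEF(wts, ef_scaled, countries(w))
  expect_equal(scaled$ef, res$country_table$ef * 3.7, tolerance = 1e-12)
})

test_that("splitting a country and recombining by area reproduces its EF", {
  eco <- makeEcoregions(2, 2, 10, origin = c(0, 0))
  ef <- data.frame(eco_id = 1:4, eco_name = letters[1:4],
                   biome_name = letters[1:4],
                   ef_raw = c(0.1, 0.2, 0.3, 0.4), ef = c(1, 2, 3, 4))
  whole <- rectLayer(list(matrix(c(3, 0, 17, 20), 1)),
                     data.frame(country = "W", iso_cc = "WW"),
                     class = "CountrySet")
  halves <- rectLayer(list(matrix(c(3, 0, 8, 20), 1),
                           matrix(c(8, 0, 17, 20), 1)),
                      data.frame(country = c("L", "R"),
                                 iso_cc = c("LL", "RR")),
                      class = "CountrySet")
  ef_whole <- countryEF(intersectionWeights(eco, whole), ef, whole)
  sub <- countryEF(intersectionWeights(eco, halves), ef, halves)
  areas <- featureAreas(halves)
  recombined <- sum(sub$ef * areas) / sum(areas)
  expect_equal(recombined, ef_whole$ef, tolerance = 1e-9)
})
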