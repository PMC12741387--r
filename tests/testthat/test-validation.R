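# Spearman rank correlation and the EF-vs-richness check.

test_that("spearmanRank handles perfect concordance and discordance", {
  up <- spearmanRank(1:4, c(10, 20, 30, 40))
  expect_identical(up@rho, 1)
  expect_gt(up@p.value, 0)
  down <- spearmanRank(1:4, c(40, 30, 20, 10))
  expect_identical(down@rho, -1)
})

test_that("rho equals the rank-then-Pearson oracle, ties included", {
  set.seed(17)
  for (rep in 1:25) {
    x <- sample(1:8, 20, replace = TRUE)   # heavy ties
    y <- rnorm(20) + x / 4
    got <- spearmanRank(x, y)
    ref <- cor(rank(x, ties.method = "average"),
               rank(y, ties.method = "average"))
    expect_equal(got@rho, ref, tolerance = 1e-12)
  }
})

test_that("rho matches the oracle for every permutation at small n", {
  perms <- ecofactor:::.permutations(5L)
  x <- c(2, 7, 1, 9, 4)
  for (i in seq_len(nrow(perms))) {
    y <- x[perms[i, ]]
    got <- spearmanRank(x, y)@rho
    ref <- cor(rank(x), rank(y))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("p-value follows the t approximation and is monotone in |rho|", {
  set.seed(5)
  x <- rnorm(30)
  y <- x + rnorm(30, sd = 2)
  got <- spearmanRank(x, y)
  rho <- got@rho
  tt <- rho * sqrt((30 - 2) / (1 - rho^2))
  expect_equal(got@p.value, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
  # independent oracle: base cor.test's t-based p for Spearman-like check
  # (applied to ranks via Pearson machinery)
  ref <- cor.test(rank(x), rank(y))$p.value
  expect_equal(got@p.value, ref, tolerance = 1e-9)
  # stronger monotone relationship -> smaller p at fixed n
  y2 <- x + rnorm(30, sd = 0.1)
  expect_lt(spearmanRank(x, y2)@p.value, got@p.value)
})

test_that("exact permutation p-value agrees with enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  got <- spearmanRank(x, y, exact = TRUE)
  # enumerate independently
  perms <- ecofactor:::.permutations(5L)
  stats_all <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
  ref <- mean(abs(stats_all) >= abs(cor(rank(x), rank(y))) - 1e-12)
  expect_equal(got@p.value, ref)
  expect_error(spearmanRank(1:12, 12:1, exact = TRUE), "n <= 10")
})

test_that("spearmanRank is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- runif(40); y <- runif(40)
  base <- spearmanRank(x, y)@rho
  expect_equal(spearmanRank(exp(3 * x), y)@rho, base, tolerance = 1e-12)
  expect_equal(spearmanRank(x, y^3 + 10)@rho, base, tolerance = 1e-12)
  expect_equal(spearmanRank(-x, y)@rho, -base, tolerance = 1e-12)
})

test_that("spearmanRank rejects invalid input", {
  expect_error(spearmanRank(1:3, 1:4), "equal length")
  expect_error(spearmanRank(1:2, 1:2), "at least 3")
  expect_error(spearmanRank(c(1, 1, 1), 1:3), "zero variance")
  expect_error(spearmanRank(c(1, NA, 3), 1:3), "finite")
})

test_that("validateEF pairs zonal richness with EF per ecoregion", {
  w <- simulateWorld(4, 4, n_countries = 2, pixels_per_cell = 6, seed = 23,
                     noise_sd = 0)
  res <- suppressMessages(runWorldPipeline(w))
  # noise-free richness is a positive linear transform of the EF truth
  expect_identical(res$correlation@rho, 1)
  # reversed richness gives rho = -1
  tr <- truthEF(w)
  rev_rich <- makeRichness(ecoregions(w),
                           setNames(-tr$ef, tr$eco_id),
                           noise_sd = 0, pixels_per_cell = 6, seed = 1)
  flipped <- validateEF(res$ef_table, rev_rich, ecoregions(w))
  expect_identical(flipped@rho, -1)
  # deterministic under reruns with noise
  wn <- simulateWorld(4, 4, n_countries = 2, pixels_per_cell = 6,
                      seed = 23, noise_sd = 200)
  r1 <- validateEF(res$ef_table, wn@richness, ecoregions(w))
  r2 <- validateEF(res$ef_table, wn@richness, ecoregions(w))
  expect_identical(r1@rho, r2@rho)
  expect_true(r1@rho > 0 && r1@rho < 1)
})

test_that("validateEF requires at least three pairable ecoregions", {
  w <- simulateWorld(4, 4, n_countries = 2, pixels_per_cell = 6, seed = 23)
  res <- suppressMessages(runWorldPipeline(w))
  expect_error(validateEF(res$ef_table[0, ], w@richness, ecoregions(w)),
               "empty")
  # richness raster far away: nothing pairable
  far <- gridRaster(matrix(1, 4, 4), xmin = 160, ymax = 80,
                    xres = 1, yres = 1)
  expect_error(validateEF(res$ef_table, far, ecoregions(w)), "fewer than 3")
})
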