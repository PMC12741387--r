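# Shared fixtures, generated in code.

# Small fully-specified world: 2x3 ecoregion grid, explicit targets.
makeTestWorld <- function(pixels_per_cell = 10L, seed = 11L) {
  eco <- makeEcoregions(2, 3, 10, origin = c(0, 0), seed = seed)
  ids <- featureData(eco)$eco_id
  sgf <- setNames(c(1, 0, 0.5, 0.25, 0.75, 0.1), ids)
  sw  <- setNames(c(0, 1, 0.25, 0.5, 0.1, 0.3), ids)
  sra <- setNames(c(0.2, 0.4, 0.6, 0.8, 1, 0.05), ids)
  gep <- matrix(c(0, 0, 0, 0,
                  0.1, 0.2, 0.3, 0.4,
                  0.05, 0.05, 0.05, 0.05,
                  0.2, 0.1, 0, 0.1,
                  0.3, 0.3, 0.3, 0.3,
                  0.01, 0.02, 0.03, 0.04), 6, 4, byrow = TRUE)
  lc <- makeLandcover(eco, sgf, pixels_per_cell, seed)
  wet <- makeCoverageLayer(eco, sw, "wetland", seed)
  rdl <- makeCoverageLayer(eco, sra, "roadless", seed)
  g <- makeGep(eco, gep, pixels_per_cell, seed)
  list(eco = eco, lc = lc, wet = wet, rdl = rdl, gep = g,
       sgf = sgf, sw = sw, sra = sra, gep_target = gep)
}

# Brute-force union area of rectangles by fine-grid pixel counting;
# independent of the coordinate-compression implementation.
pixelUnionArea <- function(rects, n = 400L) {
  x0 <- min(rects[, 1]); x1 <- max(rects[, 3])
  y0 <- min(rects[, 2]); y1 <- max(rects[, 4])
  xs <- seq(x0, x1, length.out = n + 1); xs <- (xs[-1] + xs[-(n + 1)]) / 2
  ys <- seq(y0, y1, length.out = n + 1); ys <- (ys[-1] + ys[-(n + 1)]) / 2
  px <- (x1 - x0) / n; py <- (y1 - y0) / n
  covered <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(rects))) {
    ix <- xs >= rects[i, 1] & xs < rects[i, 3]
    iy <- ys >= rects[i, 2] & ys < rects[i, 4]
    covered[ix, iy] <- TRUE
  }
  sum(covered) * px * py
}
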