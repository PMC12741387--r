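## Synthetic-world generator: a miniature planet of rectangle ecoregions
## with rasters and coverage layers painted to exactly known indicator
## values, standing in for the global land-cover / wetland / extinction-
## probability / roadless datasets the real factor is computed from.

.BIOMES <- c(
  "Tropical & Subtropical Moist Broadleaf Forests",
  "Temperate Broadleaf & Mixed Forests",
  "Boreal Forests/Taiga",
  "Tropical & Subtropical Grasslands, Savannas & Shrublands",
  "Temperate Grasslands, Savannas & Shrublands",
  "Montane Grasslands & Shrublands",
  "Deserts & Xeric Shrublands",
  "Mediterranean Forests, Woodlands & Scrub",
  "Tundra",
  "Mangroves")

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG
## state afterwards so generators are pure functions of their arguments.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.checkShares <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

## Match a named target vector against ecoregion ids; unnamed vectors of
## the right length are taken in layer order.
.targetsFor <- function(targets, ids, what) {
  if (is.null(names(targets))) {
    if (length(targets) != length(ids))
      stop(what, ": unnamed targets must have one value per ecoregion",
           call. = FALSE)
    names(targets) <- as.character(ids)
  }
  miss <- setdiff(as.character(ids), names(targets))
  if (length(miss))
    stop(what, ": no target for ecoregion id(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  targets[as.character(ids)]
}

#' Generate a rectangular tessellation of synthetic ecoregions
#'
#' Builds an `n_rows` x `n_cols` grid of square ecoregion polygons of side
#' `cell_size_deg` degrees, anchored at `origin` (lower-left corner).  The
#' polygons are pairwise disjoint and tile the world rectangle exactly, so
#' every downstream area computation has a closed form.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size_deg cell side length in degrees (> 0).
#' @param origin numeric length-2, lon/lat of the lower-left corner.
#' @param seed integer; kept for interface symmetry (the tessellation is
#'   deterministic).
#' @return An [EcoregionSet-class] with unique `eco_id`, generated
#'   `eco_name` and `biome_name` cycled through a fixed biome list.
#' @examples
#' eco <- makeEcoregions(2, 3, 5)
#' length(eco)          # 6 polygons
#' featureAreas(eco)    # 25 square degrees each
#' @export
makeEcoregions <- function(n_rows, n_cols, cell_size_deg,
                           origin = c(0, 0), seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_deg > 0,
            length(origin) == 2L)
  x0 <- origin[1L]; y0 <- origin[2L]
  x1 <- x0 + n_cols * cell_size_deg
  y1 <- y0 + n_rows * cell_size_deg
  if (x0 < -180 || x1 > 180 || y0 < -90 || y1 > 90)
    stop("grid exceeds valid lon/lat bounds ",
         "(lon in [-180, 180], lat in [-90, 90])", call. = FALSE)
  rects <- vector("list", n_rows * n_cols)
  ids <- integer(n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      k <- k + 1L
      rects[[k]] <- .asRects(c(x0 + (c - 1L) * cell_size_deg,
                               y0 + (r - 1L) * cell_size_deg,
                               x0 + c * cell_size_deg,
                               y0 + r * cell_size_deg))
      ids[k] <- k
    }
  }
  dat <- data.frame(
    eco_id = ids,
    eco_name = sprintf("Synthetic ecoregion %03d", ids),
    biome_name = .BIOMES[(ids - 1L) %% length(.BIOMES) + 1L],
    stringsAsFactors = FALSE)
  rectLayer(rects, dat, crs = "EPSG:4326", class = "EcoregionSet")
}

#' Generate synthetic country polygons over an ecoregion grid
#'
#' Partitions the world rectangle of `ecoregions` into `n_countries`
#' vertical strips whose internal boundaries are offset from the ecoregion
#' grid lines, so countries straddle several ecoregions whenever there are
#' fewer countries than ecoregions.  All geometry is rectangles, so every
#' ecoregion-country intersection area has a closed form.
#'
#' @param ecoregions an [EcoregionSet-class] from [makeEcoregions()].
#' @param n_countries number of countries (>= 1).
#' @param seed integer seed controlling the boundary offsets.
#' @return A [CountrySet-class] with `country` names and synthetic
#'   `iso_cc` codes.
#' @examples
#' eco <- makeEcoregions(2, 3, 5)
#' cty <- makeCountries(eco, 2)
#' sum(featureAreas(cty)) == sum(featureAreas(eco))
#' @export
makeCountries <- function(ecoregions, n_countries, seed = 1L) {
  stopifnot(is(ecoregions, "EcoregionSet"), n_countries >= 1)
  all_r <- do.call(rbind, geometry(ecoregions))
  x0 <- min(all_r[, 1L]); x1 <- max(all_r[, 3L])
  y0 <- min(all_r[, 2L]); y1 <- max(all_r[, 4L])
  n <- as.integer(n_countries)
  if (n == 1L) {
    bounds <- c(x0, x1)
  } else {
    width <- (x1 - x0) / n
    ## offset interior boundaries off the grid lines by a seeded fraction
    ## of the strip width (20-45%), keeping them strictly increasing
    off <- .withSeed(seed, stats::runif(n - 1L, 0.20, 0.45)) * width
    bounds <- c(x0, x0 + width * seq_len(n - 1L) - width / 2 + off, x1)
  }
  rects <- lapply(seq_len(n), function(k)
    .asRects(c(bounds[k], y0, bounds[k + 1L], y1)))
  dat <- data.frame(
    country = sprintf("Synthetic country %02d", seq_len(n)),
    iso_cc = sprintf("S%02d", seq_len(n)),
    stringsAsFactors = FALSE)
  rectLayer(rects, dat, crs = crsName(ecoregions), class = "CountrySet")
}

## Pixel-index windows of an ecoregion grid cell within an aligned raster.
.regionPixelWindow <- function(rect, xmin, ymax, xres, yres, nr, nc) {
  cx <- xmin + (seq_len(nc) - 0.5) * xres
  cy <- ymax - (seq_len(nr) - 0.5) * yres
  list(cols = which(cx >= rect[1L] & cx < rect[3L]),
       rows = which(cy >= rect[2L] & cy < rect[4L]))
}

#' Paint a categorical land-cover raster with exact class shares
#'
#' Generates a raster aligned to the ecoregion grid (pixel edges coincide
#' with ecoregion edges) where, within each ecoregion, the fraction of
#' pixels carrying a grassland or forest code equals the nearest achievable
#' fraction to the requested target (`round(target * P) / P` for `P`
#' pixels).  Painted pixel positions are shuffled with the seed; class
#' codes are 0 (other), 1 (grassland), 2 (forest).
#'
#' @param ecoregions an [EcoregionSet-class] grid from [makeEcoregions()].
#' @param target_sgf numeric vector of target shares in \[0, 1\], named by
#'   `eco_id` (or unnamed, in layer order).
#' @param pixels_per_cell pixels along each side of one ecoregion cell
#'   (>= 2).
#' @param seed integer seed for pixel placement.
#' @return A list with `raster` (the categorical [GridRaster-class]) and
#'   `achieved` (named numeric, the post-discretization shares — these are
#'   the ground truth, not the targets).
#' @export
makeLandcover <- function(ecoregions, target_sgf, pixels_per_cell, seed = 1L) {
  stopifnot(is(ecoregions, "EcoregionSet"), pixels_per_cell >= 2)
  ids <- featureData(ecoregions)$eco_id
  target <- .checkShares(.targetsFor(target_sgf, ids, "target_sgf"),
                         "target_sgf")
  ras <- .emptyWorldRaster(ecoregions, pixels_per_cell)
  v <- ras@values
  nr <- nrow(v); nc <- ncol(v)
  achieved <- stats::setNames(numeric(length(ids)), as.character(ids))
  .withSeed(seed, {
    for (i in seq_along(ids)) {
      w <- .regionPixelWindow(geometry(ecoregions)[[i]], ras@xmin, ras@ymax,
                              ras@xres, ras@yres, nr, nc)
      cells <- as.vector(outer(w$rows, (w$cols - 1L) * nr, `+`))
      P <- length(cells)
      k <- as.integer(round(target[i] * P))
      pick <- if (k > 0L) sample(cells, k) else integer(0)
      v[cells] <- 0
      if (k > 0L) {
        ## split painted pixels between forest and grassland
        nf <- ceiling(k / 2)
        v[pick[seq_len(nf)]] <- 2
        if (k > nf) v[pick[(nf + 1L):k]] <- 1
      }
      achieved[i] <- k / P
    }
  })
  ras@values <- v
  list(raster = ras, achieved = achieved)
}

## Blank raster covering the world rectangle of a grid EcoregionSet with
## pixels_per_cell pixels per ecoregion side, edges aligned to cell edges.
.emptyWorldRaster <- function(ecoregions, pixels_per_cell, fill = 0) {
  all_r <- do.call(rbind, geometry(ecoregions))
  x0 <- min(all_r[, 1L]); x1 <- max(all_r[, 3L])
  y0 <- min(all_r[, 2L]); y1 <- max(all_r[, 4L])
  cell <- all_r[1L, 3L] - all_r[1L, 1L]
  res <- cell / pixels_per_cell
  nc <- as.integer(round((x1 - x0) / res))
  nr <- as.integer(round((y1 - y0) / res))
  gridRaster(matrix(fill, nr, nc), xmin = x0, ymax = y1,
             xres = res, yres = res, crs = crsName(ecoregions))
}

#' Generate a coverage layer (wetlands or roadless areas) with exact shares
#'
#' For each ecoregion with a positive target share, emits one sub-rectangle
#' centred in the ecoregion with both sides shrunk by `sqrt(share)`, so its
#' area is exactly `share` times the ecoregion's planar extent.  A share of
#' 0 emits no polygon; a share of 1 reproduces the ecoregion itself.
#'
#' @param ecoregions an [EcoregionSet-class].
#' @param target_share numeric shares in \[0, 1\] named by `eco_id` (or
#'   unnamed, in layer order).
#' @param kind `"wetland"` or `"roadless"` (attribute label only).
#' @param seed integer; kept for interface symmetry (construction is
#'   deterministic).
#' @return A list with `layer` (a [RectLayer-class]) and `achieved`
#'   (named numeric; equals the target exactly).
#' @export
makeCoverageLayer <- function(ecoregions, target_share,
                              kind = c("wetland", "roadless"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is(ecoregions, "EcoregionSet"))
  ids <- featureData(ecoregions)$eco_id
  share <- .checkShares(.targetsFor(target_share, ids, "target_share"),
                        "target_share")
  keep <- which(share > 0)
  rects <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    r <- geometry(ecoregions)[[i]]
    f <- sqrt(share[i])
    cx <- (r[1L] + r[3L]) / 2; cy <- (r[2L] + r[4L]) / 2
    hw <- (r[3L] - r[1L]) / 2 * f; hh <- (r[4L] - r[2L]) / 2 * f
    rects[[j]] <- .asRects(c(cx - hw, cy - hh, cx + hw, cy + hh))
  }
  dat <- data.frame(eco_id = ids[keep], kind = rep(kind, length(keep)),
                    stringsAsFactors = FALSE)
  list(layer = rectLayer(rects, dat, crs = crsName(ecoregions)),
       achieved = stats::setNames(as.numeric(share), as.character(ids)))
}

#' Generate per-taxon extinction-probability rasters
#'
#' Each of the four taxon rasters (amphibians, birds, reptiles, mammals) is
#' constant within every ecoregion at the requested per-taxon value, so the
#' zonal mean is exact and the composite ground truth is the row sum.
#'
#' @param ecoregions an [EcoregionSet-class] grid.
#' @param target_gep numeric matrix (or data.frame) with one row per
#'   ecoregion and four columns (amphibians, birds, reptiles, mammals) of
#'   non-negative values; rownames may carry `eco_id`s.
#' @param pixels_per_cell pixels along each side of one ecoregion cell.
#' @param seed integer; kept for interface symmetry.
#' @return A list with `rasters` (named list of four [GridRaster-class])
#'   and `achieved` (named numeric composite = row sums).
#' @export
makeGep <- function(ecoregions, target_gep, pixels_per_cell, seed = 1L) {
  stopifnot(is(ecoregions, "EcoregionSet"), pixels_per_cell >= 1)
  taxa <- c("amphibians", "birds", "reptiles", "mammals")
  ids <- featureData(ecoregions)$eco_id
  m <- as.matrix(target_gep)
  if (ncol(m) != 4L)
    stop("target_gep must have four columns (one per taxon)", call. = FALSE)
  if (nrow(m) != length(ids))
    stop("target_gep must have one row per ecoregion", call. = FALSE)
  if (any(!is.finite(m) | m < 0))
    stop("target_gep values must be non-negative", call. = FALSE)
  colnames(m) <- taxa
  rasters <- stats::setNames(vector("list", 4L), taxa)
  for (t in seq_along(taxa)) {
    ras <- .emptyWorldRaster(ecoregions, pixels_per_cell)
    v <- ras@values
    for (i in seq_along(ids)) {
      w <- .regionPixelWindow(geometry(ecoregions)[[i]], ras@xmin, ras@ymax,
                              ras@xres, ras@yres, nrow(v), ncol(v))
      v[w$rows, w$cols] <- m[i, t]
    }
    ras@values <- v
    rasters[[t]] <- ras
  }
  list(rasters = rasters,
       achieved = stats::setNames(rowSums(m), as.character(ids)))
}

#' Generate a species-richness raster tied to an EF ground truth
#'
#' Paints a per-ecoregion constant raster equal to a monotone (linear,
#' positive-slope) transform of the supplied EF truth plus seeded Gaussian
#' noise.  With `noise_sd = 0` the layer is perfectly rank-concordant with
#' the EF, so the downstream Spearman correlation is exactly 1 when the EF
#' values are distinct; passing `-ef_truth` reverses the ranking.
#'
#' @param ecoregions an [EcoregionSet-class] grid.
#' @param ef_truth numeric EF values named by `eco_id` (or unnamed, in
#'   layer order).
#' @param noise_sd standard deviation of the Gaussian noise, on the scale
#'   of the transformed richness values (>= 0).
#' @param pixels_per_cell pixels along each side of one ecoregion cell.
#' @param seed integer seed for the noise.
#' @param scale positive slope of the linear transform (default 1000
#'   richness units per EF unit).
#' @return A continuous [GridRaster-class].
#' @export
makeRichness <- function(ecoregions, ef_truth, noise_sd = 0,
                         pixels_per_cell = 4L, seed = 1L, scale = 1000) {
  stopifnot(is(ecoregions, "EcoregionSet"), noise_sd >= 0, scale > 0)
  ids <- featureData(ecoregions)$eco_id
  ef <- .targetsFor(ef_truth, ids, "ef_truth")
  vals <- .withSeed(seed,
                    scale * ef + stats::rnorm(length(ef), 0, noise_sd))
  ras <- .emptyWorldRaster(ecoregions, pixels_per_cell)
  v <- ras@values
  for (i in seq_along(ids)) {
    w <- .regionPixelWindow(geometry(ecoregions)[[i]], ras@xmin, ras@ymax,
                            ras@xres, ras@yres, nrow(v), ncol(v))
    v[w$rows, w$cols] <- vals[i]
  }
  ras@values <- v
  ras
}

#' Simulate a complete synthetic world with known ground truth
#'
#' Generates the full input bundle the Ecoregion Factor pipeline consumes:
#' an ecoregion grid, offset country strips, a categorical land-cover
#' raster, wetland and roadless coverage layers, four per-taxon
#' extinction-probability rasters and a species-richness layer derived from
#' the closed-form EF of the painted truth.  Indicator targets are drawn
#' from ranges typical of the real global layers: grassland+forest and
#' roadless shares span most of \[0, 1\] across ecoregions, wetland shares
#' are small (Ramsar sites cover minor fractions), and per-taxon extinction
#' probabilities are small positive numbers.
#'
#' @param n_rows,n_cols ecoregion grid dimensions.
#' @param cell_size_deg ecoregion cell side in degrees.
#' @param origin lon/lat of the grid's lower-left corner.
#' @param n_countries number of synthetic countries.
#' @param pixels_per_cell raster pixels per ecoregion side.
#' @param noise_sd Gaussian noise on the richness layer, in richness units
#'   (the noise-free layer spans `scale` times the EF truth range).
#' @param seed integer master seed; the same seed reproduces the world
#'   bit-for-bit.
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 5, seed = 7)
#' head(worldTruth(w))
#' @export
simulateWorld <- function(n_rows = 10L, n_cols = 10L, cell_size_deg = NULL,
                          origin = NULL, n_countries = 5L,
                          pixels_per_cell = 10L, noise_sd = 100,
                          seed = 1L) {
  if (is.null(cell_size_deg))
    cell_size_deg <- min(150 / n_cols, 150 / n_rows)
  if (is.null(origin))
    origin <- c(-n_cols * cell_size_deg / 2, -n_rows * cell_size_deg / 2)
  eco <- makeEcoregions(n_rows, n_cols, cell_size_deg, origin, seed)
  n <- length(eco)
  ids <- featureData(eco)$eco_id
  tg <- .withSeed(seed, list(
    sgf = stats::runif(n, 0.05, 0.95),
    sw  = stats::runif(n, 0.00, 0.40),
    gep = matrix(stats::runif(4L * n, 0.00, 0.30), n, 4L),
    sra = stats::runif(n, 0.05, 0.95)))
  cty <- makeCountries(eco, n_countries, seed + 1L)
  lc <- makeLandcover(eco, stats::setNames(tg$sgf, ids), pixels_per_cell,
                      seed + 2L)
  wet <- makeCoverageLayer(eco, stats::setNames(tg$sw, ids), "wetland",
                           seed + 3L)
  rdl <- makeCoverageLayer(eco, stats::setNames(tg$sra, ids), "roadless",
                           seed + 4L)
  gep <- makeGep(eco, tg$gep, pixels_per_cell, seed + 5L)
  truth <- data.frame(
    eco_id = ids,
    sgf_true = as.numeric(lc$achieved),
    sw_true = as.numeric(wet$achieved),
    gep_true = as.numeric(gep$achieved),
    sra_true = as.numeric(rdl$achieved))
  ef_true <- .truthEFValues(truth)
  rich <- makeRichness(eco, stats::setNames(ef_true$ef, ids),
                       noise_sd = noise_sd,
                       pixels_per_cell = pixels_per_cell, seed = seed + 6L)
  new("SyntheticWorld", ecoregions = eco, countries = cty,
      landcover = lc$raster, wetlands = wet$layer, roadless = rdl$layer,
      gep = gep$rasters, richness = rich, truth = truth,
      seed = as.integer(seed))
}

## Closed-form EF from a truth table: min-max normalize the four achieved
## indicators, aggregate, min-scale.  This is the oracle the pipeline's
## raster/vector route is compared against.
.truthEFValues <- function(truth) {
  norm <- data.frame(
    sgf = minmaxScale(truth$sgf_true),
    sw = minmaxScale(truth$sw_true),
    gep = minmaxScale(truth$gep_true),
    sra = minmaxScale(truth$sra_true))
  raw <- efRaw(norm$sgf, norm$sw, norm$gep, norm$sra)
  data.frame(eco_id = truth$eco_id, ef_raw = raw, ef = scaleByMin(raw))
}

#' Closed-form EF table from a synthetic world's ground truth
#'
#' Computes the Ecoregion Factor directly from the stored achieved
#' indicator values (no rasters or overlays involved): min-max
#' normalization, root-mean-square aggregation, min-scaling.  Used as the
#' analytic oracle for end-to-end pipeline recovery.
#'
#' @param world a [SyntheticWorld-class].
#' @return data.frame with `eco_id`, `ef_raw`, `ef`.
#' @export
truthEF <- function(world) {
  stopifnot(is(world, "SyntheticWorld"))
  .truthEFValues(worldTruth(world))
}
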