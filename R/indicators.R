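## Per-ecoregion indicator extraction: class shares and zonal means from
## rasters (pixel-center-in-polygon rule) and area shares from polygon
## overlays (dissolve-then-intersect, equal-area frame).

.checkSameCRS <- function(a, b) {
  if (!identical(crsName(a), crsName(b)))
    stop("CRS mismatch: ", crsName(a), " vs ", crsName(b), call. = FALSE)
}

## Linear indices (into the value matrix) of all cells whose center lies
## inside any rectangle of a feature.  Half-open [min, max) on both axes;
## with grid-aligned rasters centers never fall on region edges, so the
## convention carries no bias.
.cellsInFeature <- function(raster, rects) {
  v <- raster@values
  nr <- nrow(v); nc <- ncol(v)
  cx <- raster@xmin + (seq_len(nc) - 0.5) * raster@xres
  cy <- raster@ymax - (seq_len(nr) - 0.5) * raster@yres
  idx <- integer(0)
  for (i in seq_len(nrow(rects))) {
    cols <- which(cx >= rects[i, 1L] & cx < rects[i, 3L])
    rows <- which(cy >= rects[i, 2L] & cy < rects[i, 4L])
    if (length(cols) && length(rows))
      idx <- c(idx, as.vector(outer(rows, (cols - 1L) * nr, `+`)))
  }
  unique(idx)
}

#' Fraction of raster cells in a class set, per ecoregion
#'
#' For each region, counts the cells whose center lies inside the region
#' and whose value belongs to `classes`, divided by all cells whose center
#' lies inside the region.  A region covered by no cell center is `NA`
#' (missing), feeding the valid-data retention rule.
#'
#' @param raster a categorical [GridRaster-class].
#' @param classes non-empty vector of class codes counted as hits (for the
#'   grassland+forest share: `c(1, 2)` with the synthetic generator's
#'   coding).
#' @param regions an [EcoregionSet-class] in the same CRS.
#' @return Named numeric vector of fractions in \[0, 1\] (names =
#'   `eco_id`), `NA` where a region has no covering cells.
#' @export
classShare <- function(raster, classes, regions) {
  stopifnot(is(raster, "GridRaster"), is(regions, "EcoregionSet"))
  if (length(classes) == 0L)
    stop("classes must be non-empty", call. = FALSE)
  if (length(raster@values) == 0L)
    stop("empty raster", call. = FALSE)
  .checkSameCRS(raster, regions)
  ids <- featureData(regions)$eco_id
  out <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (i in seq_along(ids)) {
    idx <- .cellsInFeature(raster, geometry(regions)[[i]])
    if (length(idx))
      out[i] <- sum(raster@values[idx] %in% classes) / length(idx)
  }
  out
}

#' Zonal mean of a continuous raster, per ecoregion
#'
#' Mean of the cells whose center lies inside each region, excluding `NA`
#' (no-data) cells from both numerator and denominator.  Regions with no
#' valid cell are `NA`.
#'
#' @param raster a continuous [GridRaster-class].
#' @param regions an [EcoregionSet-class] in the same CRS.
#' @return Named numeric vector (names = `eco_id`).
#' @export
zonalMean <- function(raster, regions) {
  stopifnot(is(raster, "GridRaster"), is(regions, "EcoregionSet"))
  if (length(raster@values) == 0L)
    stop("empty raster", call. = FALSE)
  .checkSameCRS(raster, regions)
  ids <- featureData(regions)$eco_id
  out <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (i in seq_along(ids)) {
    idx <- .cellsInFeature(raster, geometry(regions)[[i]])
    vals <- raster@values[idx]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[i] <- mean(vals)
  }
  out
}

#' Area share of a coverage layer within each ecoregion
#'
#' Computes `area(region intersect union(cover)) / area(region)`.  The
#' cover geometries are dissolved (unioned) before intersection, so
#' self-overlapping cover features (e.g. overlapping designated wetland
#' sites) are never double-counted and the share cannot exceed 1.  Areas
#' are evaluated in an equal-area frame: planar CRS units when
#' `planar = TRUE` (exact for synthetic worlds), spherical surface areas
#' treating coordinates as lon/lat degrees otherwise.
#'
#' @param cover a [RectLayer-class] coverage layer (wetlands, roadless
#'   areas).
#' @param regions an [EcoregionSet-class] in the same CRS.
#' @param planar logical; see above.
#' @return Named numeric vector of shares in \[0, 1\] (names = `eco_id`).
#' @export
overlayShare <- function(cover, regions, planar = TRUE) {
  stopifnot(is(cover, "RectLayer"), is(regions, "EcoregionSet"))
  .checkSameCRS(cover, regions)
  cov_rects <- .frameRects(do.call(rbind, c(geometry(cover),
                                            list(.emptyRects()))), planar)
  ids <- featureData(regions)$eco_id
  out <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (i in seq_along(ids)) {
    reg <- .frameRects(geometry(regions)[[i]], planar)
    a <- .rectUnionArea(reg)
    out[i] <- if (a > 0) .rectIntersectionArea(reg, cov_rects) / a else 0
  }
  ## clamp the ulp-level float excess so shares are hard-bounded by 1
  pmin(pmax(out, 0), 1)
}

#' Composite extinction probability per ecoregion
#'
#' Zonal mean of each of the four taxon rasters (pixel-center rule,
#' ignoring no-data cells), then the sum of the four means.  A region is
#' missing (`NA`) if any taxon raster has no valid cell in it, feeding the
#' valid-data retention rule.
#'
#' @param taxon_rasters list of four co-registered continuous
#'   [GridRaster-class] objects (amphibians, birds, reptiles, mammals).
#' @param regions an [EcoregionSet-class].
#' @return Named numeric vector (names = `eco_id`).
#' @export
gepComposite <- function(taxon_rasters, regions) {
  if (length(taxon_rasters) != 4L)
    stop("taxon_rasters must contain four rasters", call. = FALSE)
  ref <- taxon_rasters[[1L]]
  for (r in taxon_rasters[-1L]) {
    if (!identical(dim(r@values), dim(ref@values)) ||
        !isTRUE(all.equal(c(r@xmin, r@ymax, r@xres, r@yres),
                          c(ref@xmin, ref@ymax, ref@xres, ref@yres))))
      stop("taxon rasters are not co-registered", call. = FALSE)
  }
  means <- lapply(taxon_rasters, zonalMean, regions = regions)
  tot <- Reduce(`+`, means)   # NA propagates: missing if any taxon missing
  tot
}

#' Assemble the per-ecoregion indicator table
#'
#' Runs the four indicator extractions — grassland+forest class share
#' (SGF), wetland overlay share (SW), composite extinction probability
#' (GEP) and roadless overlay share (SRA) — and assembles one row per
#' ecoregion.  `valid` is `TRUE` only when all four raw values are
#' present; only valid rows are retained downstream.
#'
#' @param regions an [EcoregionSet-class].
#' @param landcover categorical [GridRaster-class].
#' @param wetlands,roadless coverage [RectLayer-class] layers.
#' @param gep_rasters list of four co-registered [GridRaster-class].
#' @param classes land-cover codes counted as grassland or forest.
#' @param planar logical, equal-area frame for overlay shares (see
#'   [overlayShare()]).
#' @return data.frame with columns `eco_id`, `sgf_raw`, `sw_raw`,
#'   `gep_raw`, `sra_raw`, `valid`.
#' @examples
#' w <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 5, seed = 7)
#' tab <- assembleIndicators(ecoregions(w), w@landcover, w@wetlands,
#'                           w@roadless, w@gep)
#' head(tab)
#' @export
assembleIndicators <- function(regions, landcover, wetlands, roadless,
                               gep_rasters, classes = c(1, 2),
                               planar = TRUE) {
  stopifnot(is(regions, "EcoregionSet"))
  ids <- featureData(regions)$eco_id
  if (length(ids) == 0L)
    return(data.frame(eco_id = integer(0), sgf_raw = numeric(0),
                      sw_raw = numeric(0), gep_raw = numeric(0),
                      sra_raw = numeric(0), valid = logical(0)))
  sgf <- classShare(landcover, classes, regions)
  sw <- overlayShare(wetlands, regions, planar = planar)
  gep <- gepComposite(gep_rasters, regions)
  sra <- overlayShare(roadless, regions, planar = planar)
  tab <- data.frame(eco_id = ids,
                    sgf_raw = as.numeric(sgf), sw_raw = as.numeric(sw),
                    gep_raw = as.numeric(gep), sra_raw = as.numeric(sra))
  tab$valid <- !is.na(tab$sgf_raw) & !is.na(tab$sw_raw) &
    !is.na(tab$gep_raw) & !is.na(tab$sra_raw)
  tab
}
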