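#' @import methods
NULL

#' In-memory raster on a regular lon/lat grid
#'
#' Minimal raster container used throughout the package: a numeric matrix of
#' cell values (row 1 is the northernmost row) plus the grid georeference
#' (upper-left corner and cell resolution) and a CRS label.  Missing cells
#' are `NA`.  Categorical rasters (land cover) store integer class codes;
#' continuous rasters (extinction probability, species richness) store reals.
#'
#' @slot values numeric matrix; `values[1, 1]` is the upper-left cell.
#' @slot xmin,ymax numeric; coordinates of the grid's upper-left corner.
#' @slot xres,yres numeric; cell width and height in CRS units (positive).
#' @slot crs character; CRS label, `"EPSG:4326"` for geographic layers.
#'
#' @seealso [gridRaster()], [classShare()], [zonalMean()]
#' @exportClass GridRaster
setClass("GridRaster",
  representation(values = "matrix", xmin = "numeric", ymax = "numeric",
                 xres = "numeric", yres = "numeric", crs = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (length(object@xres) != 1L || length(object@yres) != 1L ||
        !is.finite(object@xres) || !is.finite(object@yres) ||
        object@xres <= 0 || object@yres <= 0)
      msg <- c(msg, "xres and yres must be single positive numbers")
    if (length(object@xmin) != 1L || length(object@ymax) != 1L ||
        !is.finite(object@xmin) || !is.finite(object@ymax))
      msg <- c(msg, "xmin and ymax must be single finite numbers")
    if (length(object@crs) != 1L || !nzchar(object@crs))
      msg <- c(msg, "crs must be a non-empty string")
    if (is.null(msg)) TRUE else msg
  })

#' Vector layer of axis-aligned rectangle polygons
#'
#' The package's vector container.  Each feature's geometry is a union of
#' axis-aligned rectangles (an n x 4 matrix with columns
#' `xmin, ymin, xmax, ymax`), which keeps every area, intersection and
#' overlay computation exact.  Feature attributes live in a `data.frame`
#' with one row per feature.
#'
#' @slot rects list of numeric matrices, one per feature.
#' @slot data data.frame of feature attributes, one row per feature.
#' @slot crs character CRS label.
#'
#' @seealso [rectLayer()], [EcoregionSet-class], [CountrySet-class]
#' @exportClass RectLayer
setClass("RectLayer",
  representation(rects = "list", data = "data.frame", crs = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@rects) != nrow(object@data))
      msg <- c(msg, "number of geometries must equal number of attribute rows")
    bad <- vapply(object@rects, function(m) {
      !is.matrix(m) || ncol(m) != 4L || nrow(m) == 0L || !is.numeric(m) ||
        anyNA(m) || any(m[, 3L] <= m[, 1L]) || any(m[, 4L] <= m[, 2L])
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste0("invalid geometry for feature(s): ",
                           paste(which(bad), collapse = ", ")))
    if (length(object@crs) != 1L || !nzchar(object@crs))
      msg <- c(msg, "crs must be a non-empty string")
    if (is.null(msg)) TRUE else msg
  })

#' Set of ecoregion polygons
#'
#' A [RectLayer-class] whose attribute table carries the ecoregion identity
#' columns `eco_id` (unique integer), `eco_name` and `biome_name` — the
#' spatial units on which the Ecoregion Factor is computed.
#'
#' @seealso [makeEcoregions()]
#' @exportClass EcoregionSet
setClass("EcoregionSet", contains = "RectLayer",
  validity = function(object) {
    msg <- NULL
    need <- c("eco_id", "eco_name", "biome_name")
    miss <- setdiff(need, names(object@data))
    if (length(miss))
      msg <- c(msg, paste("missing attribute column(s):",
                          paste(miss, collapse = ", ")))
    if ("eco_id" %in% names(object@data) &&
        anyDuplicated(object@data$eco_id))
      msg <- c(msg, "eco_id values must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Set of country polygons
#'
#' A [RectLayer-class] whose attribute table carries `country` (name) and a
#' unique `iso_cc` country code, used for area-weighted national
#' aggregation of the Ecoregion Factor.
#'
#' @seealso [makeCountries()], [intersectionWeights()]
#' @exportClass CountrySet
setClass("CountrySet", contains = "RectLayer",
  validity = function(object) {
    msg <- NULL
    need <- c("country", "iso_cc")
    miss <- setdiff(need, names(object@data))
    if (length(miss))
      msg <- c(msg, paste("missing attribute column(s):",
                          paste(miss, collapse = ", ")))
    if ("iso_cc" %in% names(object@data) &&
        anyDuplicated(object@data$iso_cc))
      msg <- c(msg, "iso_cc values must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic miniature planet with known indicator ground truth
#'
#' Bundles all input layers the Ecoregion Factor pipeline consumes —
#' ecoregion and country polygons, a categorical land-cover raster, wetland
#' and roadless coverage layers, four per-taxon extinction-probability
#' rasters and a species-richness raster — together with the exact
#' per-ecoregion indicator values the generator painted into them
#' (`truth`).  Pipelines run on a `SyntheticWorld` can therefore be checked
#' against closed-form expectations.
#'
#' @slot ecoregions an [EcoregionSet-class].
#' @slot countries a [CountrySet-class].
#' @slot landcover categorical [GridRaster-class] (codes: 0 other,
#'   1 grassland, 2 forest).
#' @slot wetlands,roadless coverage [RectLayer-class] layers.
#' @slot gep named list of four [GridRaster-class] objects
#'   (`amphibians`, `birds`, `reptiles`, `mammals`).
#' @slot richness continuous [GridRaster-class] for validation.
#' @slot truth data.frame with columns `eco_id`, `sgf_true`, `sw_true`,
#'   `gep_true`, `sra_true` — achieved (post-discretization) values.
#' @slot seed integer seed the world was generated from.
#'
#' @seealso [simulateWorld()], [truthEF()]
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(ecoregions = "EcoregionSet", countries = "CountrySet",
                 landcover = "GridRaster", wetlands = "RectLayer",
                 roadless = "RectLayer", gep = "list",
                 richness = "GridRaster", truth = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    taxa <- c("amphibians", "birds", "reptiles", "mammals")
    if (!identical(sort(names(object@gep)), sort(taxa)))
      msg <- c(msg, "gep must be a list named amphibians, birds, reptiles, mammals")
    else if (!all(vapply(object@gep, is, logical(1), "GridRaster")))
      msg <- c(msg, "all gep entries must be GridRaster objects")
    need <- c("eco_id", "sgf_true", "sw_true", "gep_true", "sra_true")
    miss <- setdiff(need, names(object@truth))
    if (length(miss))
      msg <- c(msg, paste("truth is missing column(s):",
                          paste(miss, collapse = ", ")))
    else {
      shares <- unlist(object@truth[c("sgf_true", "sw_true", "sra_true")])
      if (any(shares < 0 | shares > 1))
        msg <- c(msg, "truth shares must lie in [0, 1]")
      if (any(object@truth$gep_true < 0))
        msg <- c(msg, "gep_true must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Result of a Spearman rank correlation
#'
#' @slot rho numeric in \[-1, 1\]; Spearman's rank correlation coefficient
#'   (Pearson correlation of midranks).
#' @slot p.value numeric in (0, 1\]; two-sided p from the t approximation.
#' @slot n integer >= 3; number of pairs.
#'
#' @seealso [spearmanRank()], [validateEF()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(rho = "numeric", p.value = "numeric", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@rho) != 1L || !is.finite(object@rho) ||
        abs(object@rho) > 1 + 1e-12)
      msg <- c(msg, "rho must be a single number in [-1, 1]")
    if (length(object@p.value) != 1L || !is.finite(object@p.value) ||
        object@p.value <= 0 || object@p.value > 1)
      msg <- c(msg, "p.value must be a single number in (0, 1]")
    if (length(object@n) != 1L || object@n < 3L)
      msg <- c(msg, "n must be a single integer >= 3")
    if (is.null(msg)) TRUE else msg
  })
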