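#' Construct a GridRaster
#'
#' @param values numeric matrix of cell values; row 1 is the northernmost
#'   row of the grid.
#' @param xmin,ymax coordinates of the grid's upper-left corner.
#' @param xres,yres cell width and height (positive, CRS units).
#' @param crs CRS label.
#' @return A [GridRaster-class].
#' @examples
#' r <- gridRaster(matrix(1:6, 2), xmin = 0, ymax = 2, xres = 1, yres = 1)
#' dim(rasterValues(r))
#' @export
gridRaster <- function(values, xmin, ymax, xres, yres, crs = "EPSG:4326") {
  storage.mode(values) <- "double"
  new("GridRaster", values = values, xmin = as.numeric(xmin),
      ymax = as.numeric(ymax), xres = as.numeric(xres),
      yres = as.numeric(yres), crs = crs)
}

#' Construct a rectangle-polygon vector layer
#'
#' @param rects list of n x 4 numeric matrices (columns
#'   `xmin, ymin, xmax, ymax`), one per feature.
#' @param data data.frame of feature attributes (one row per feature).
#' @param crs CRS label.
#' @param class S4 class to instantiate: `"RectLayer"` or a subclass
#'   (`"EcoregionSet"`, `"CountrySet"`).
#' @return A [RectLayer-class] (or subclass).
#' @export
rectLayer <- function(rects, data, crs = "EPSG:4326", class = "RectLayer") {
  rects <- lapply(rects, .asRects)
  new(class, rects = rects, data = as.data.frame(data), crs = crs)
}

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname accessors
#' @export
setGeneric("crsName", function(x) standardGeneric("crsName"))

#' @rdname accessors
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname accessors
#' @export
setGeneric("featureAreas", function(x, planar = TRUE)
  standardGeneric("featureAreas"))

#' Accessors for spatial containers
#'
#' `geometry()` returns the list of rectangle matrices of a vector layer;
#' `featureData()` its attribute table; `crsName()` the CRS label of a
#' layer or raster; `rasterValues()` the value matrix of a
#' [GridRaster-class]; `featureAreas()` the per-feature areas, either
#' planar (CRS units squared) or on the sphere (m^2) for geographic
#' coordinates.
#'
#' @param x a [RectLayer-class] or [GridRaster-class].
#' @param planar logical; `TRUE` computes planar areas in CRS units
#'   (exact for synthetic worlds), `FALSE` spherical surface areas in m^2
#'   treating coordinates as lon/lat degrees.
#' @return See details per accessor.
#' @name accessors
#' @aliases geometry featureData crsName rasterValues featureAreas
#' @examples
#' eco <- makeEcoregions(2, 2, 10)
#' featureAreas(eco)              # planar: 100 square degrees each
#' head(featureData(eco))
NULL

#' @rdname accessors
#' @export
setMethod("geometry", "RectLayer", function(x) x@rects)

#' @rdname accessors
#' @export
setMethod("featureData", "RectLayer", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("crsName", "RectLayer", function(x) x@crs)

#' @rdname accessors
#' @export
setMethod("crsName", "GridRaster", function(x) x@crs)

#' @rdname accessors
#' @export
setMethod("rasterValues", "GridRaster", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureAreas", "RectLayer", function(x, planar = TRUE) {
  vapply(x@rects, function(m) .rectUnionArea(.frameRects(m, planar)),
         numeric(1))
})

#' @rdname accessors
#' @export
setMethod("length", "RectLayer", function(x) length(x@rects))

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat("GridRaster:", nrow(v), "x", ncol(v), "cells,",
      "res", object@xres, "x", object@yres, paste0("[", object@crs, "]\n"))
  cat("  extent: x", object@xmin, "..", object@xmin + ncol(v) * object@xres,
      " y", object@ymax - nrow(v) * object@yres, "..", object@ymax, "\n")
  cat("  values:", sum(!is.na(v)), "valid /", length(v), "cells\n")
})

setMethod("show", "RectLayer", function(object) {
  cat(class(object), "with", length(object@rects), "feature(s)",
      paste0("[", object@crs, "]\n"))
  if (nrow(object@data)) {
    cat("  attributes:", paste(names(object@data), collapse = ", "), "\n")
    print(utils::head(object@data, 4L))
    if (nrow(object@data) > 4L) cat("  ...\n")
  }
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld (seed ", object@seed, "): ",
      length(object@ecoregions), " ecoregions, ",
      length(object@countries), " countries\n", sep = "")
  cat("  landcover: ", paste(dim(object@landcover@values), collapse = " x "),
      " px; gep taxa: ", paste(names(object@gep), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman rank correlation: rho = %.4f, p = %.3g, n = %d\n",
              object@rho, object@p.value, object@n))
})

#' @rdname worldAccessors
#' @export
setGeneric("worldTruth", function(x) standardGeneric("worldTruth"))

#' @rdname worldAccessors
#' @export
setGeneric("ecoregions", function(x) standardGeneric("ecoregions"))

#' @rdname worldAccessors
#' @export
setGeneric("countries", function(x) standardGeneric("countries"))

#' Accessors for SyntheticWorld components
#'
#' @param x a [SyntheticWorld-class].
#' @return `worldTruth()` the ground-truth indicator data.frame;
#'   `ecoregions()`/`countries()` the polygon layers.
#' @name worldAccessors
#' @aliases worldTruth ecoregions countries
NULL

#' @rdname worldAccessors
#' @export
setMethod("worldTruth", "SyntheticWorld", function(x) x@truth)

#' @rdname worldAccessors
#' @export
setMethod("ecoregions", "SyntheticWorld", function(x) x@ecoregions)

#' @rdname worldAccessors
#' @export
setMethod("countries", "SyntheticWorld", function(x) x@countries)
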