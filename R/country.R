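#' Ecoregion-country intersection areas
#'
#' Computes the pairwise intersection area of every country with every
#' ecoregion in the equal-area frame.  Zero-area (point or line contact)
#' intersections are omitted, as are floating-point slivers smaller than
#' `1e-10` of the country's area.
#'
#' @param ecoregions an [EcoregionSet-class].
#' @param countries a [CountrySet-class] in the same CRS.
#' @param planar logical; planar areas in CRS units when `TRUE`, spherical
#'   surface areas (m^2) for lon/lat coordinates otherwise.
#' @return data.frame with columns `iso_cc`, `eco_id`, `area`.
#' @export
intersectionWeights <- function(ecoregions, countries, planar = TRUE) {
  stopifnot(is(ecoregions, "EcoregionSet"), is(countries, "CountrySet"))
  .checkSameCRS(ecoregions, countries)
  eco_rects <- lapply(geometry(ecoregions), .frameRects, planar = planar)
  cty_rects <- lapply(geometry(countries), .frameRects, planar = planar)
  eco_ids <- featureData(ecoregions)$eco_id
  iso <- featureData(countries)$iso_cc
  rows <- list()
  for (c_i in seq_along(cty_rects)) {
    c_area <- .rectUnionArea(cty_rects[[c_i]])
    for (e_i in seq_along(eco_rects)) {
      a <- .rectIntersectionArea(cty_rects[[c_i]], eco_rects[[e_i]])
      if (a > 1e-10 * c_area)
        rows[[length(rows) + 1L]] <-
          data.frame(iso_cc = iso[c_i], eco_id = eco_ids[e_i], area = a,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(iso_cc = character(0), eco_id = integer(0),
                      area = numeric(0)))
  do.call(rbind, rows)
}

#' Area-weighted country EF
#'
#' National Ecoregion Factor as the area-weighted mean of the min-scaled
#' EF over all retained (EF-bearing) ecoregions intersecting the country:
#' `ef = sum(w_i * EF_i) / sum(w_i)` with `w_i` the intersection areas.
#' Country area falling in non-retained ecoregions is excluded from both
#' numerator and denominator; countries whose entire area lies in
#' non-retained ecoregions are omitted rather than imputed.
#'
#' @param weights data.frame from [intersectionWeights()].
#' @param ef_table data.frame from [computeEFTable()].
#' @param countries a [CountrySet-class] supplying names and codes.
#' @return data.frame with columns `country`, `iso_cc`, `ef`, one row per
#'   country with at least one retained intersecting ecoregion.
#' @examples
#' w <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 5, seed = 7)
#' ind <- assembleIndicators(ecoregions(w), w@landcover, w@wetlands,
#'                           w@roadless, w@gep)
#' ef <- computeEFTable(normalizeIndicators(ind), ecoregions(w))
#' wts <- intersectionWeights(ecoregions(w), countries(w))
#' countryEF(wts, ef, countries(w))
#' @export
countryEF <- function(weights, ef_table, countries) {
  stopifnot(is(countries, "CountrySet"))
  if (nrow(ef_table) == 0L)
    stop("ef_table is empty", call. = FALSE)
  w <- weights[weights$eco_id %in% ef_table$eco_id, , drop = FALSE]
  w$ef <- ef_table$ef[match(w$eco_id, ef_table$eco_id)]
  cd <- featureData(countries)
  out <- lapply(seq_len(nrow(cd)), function(i) {
    wi <- w[w$iso_cc == cd$iso_cc[i], , drop = FALSE]
    if (nrow(wi) == 0L) return(NULL)   # no retained ecoregion coverage
    data.frame(country = cd$country[i], iso_cc = cd$iso_cc[i],
               ef = sum(wi$area * wi$ef) / sum(wi$area),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    data.frame(country = character(0), iso_cc = character(0),
               ef = numeric(0))
  else out
}
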