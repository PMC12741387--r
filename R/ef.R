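#' Raw Ecoregion Factor from four normalized indicators
#'
#' Aggregates the normalized share of grassland and forest (SGF), share of
#' wetlands (SW), composite global extinction probability (GEP) and share
#' of roadless area (SRA) into the raw Ecoregion Factor:
#'
#' \deqn{EF = 1 - \sqrt{\tfrac{1}{4}\left[(1-SGF)^2 + (1-SW)^2 +
#'   (1-GEP)^2 + (1-SRA)^2\right]}}
#'
#' i.e. one minus the root mean square of the four indicator complements —
#' a fuzzy-logic-style aggregation with equal weights that penalizes a
#' severely degraded value in any single dimension harder than an
#' arithmetic mean would.  The result lies in \[0, 1\], is symmetric in
#' its arguments and non-decreasing in each.
#'
#' @param sgf,sw,gep,sra numeric vectors in \[0, 1\] (recycled to a common
#'   length).
#' @return Numeric vector of raw EF values in \[0, 1\].
#' @examples
#' efRaw(1, 1, 1, 1)          # 1
#' efRaw(0.5, 0.5, 0.5, 0.5)  # 0.5
#' efRaw(1, 1, 1, 0)          # 0.5
#' @export
efRaw <- function(sgf, sw, gep, sra) {
  m <- cbind(sgf, sw, gep, sra)
  if (any(!is.finite(m)))
    stop("indicator values must be finite", call. = FALSE)
  if (any(m < 0 | m > 1))
    stop("indicator values must lie in [0, 1]", call. = FALSE)
  1 - sqrt(rowMeans((1 - m)^2))
}

#' Scale raw EF values by the set minimum
#'
#' Divides every raw EF by the minimum of the set (or by `ref_min` when
#' supplied), converting the factors into dimensionless multipliers: the
#' least-valued ecoregion becomes the reference baseline 1 and every other
#' ecoregion a multiple of it.  Ratios between ecoregions are preserved.
#'
#' `ref_min` exists to pin an external reference minimum — e.g. the 0.037
#' of the published 2022 global dataset — so a subset can be expressed on
#' the deposit's scale; by default the observed minimum of the data at
#' hand is used, since the reference value is a property of a particular
#' dataset, not of the method.
#'
#' @param values numeric vector of raw EF values, all > 0.
#' @param ref_min optional positive reference minimum to divide by.
#' @return Numeric vector of min-scaled EF values (minimum exactly 1 when
#'   `ref_min` is `NULL`).
#' @examples
#' scaleByMin(c(0.2, 0.1, 0.4))  # 2, 1, 4
#' @export
scaleByMin <- function(values, ref_min = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("no values to scale", call. = FALSE)
  if (any(!is.finite(values) | values <= 0))
    stop("all raw EF values must be positive and finite", call. = FALSE)
  m <- if (is.null(ref_min)) min(values) else as.numeric(ref_min)
  if (!is.finite(m) || m <= 0)
    stop("ref_min must be positive", call. = FALSE)
  values / m
}

#' Compute the per-ecoregion EF table
#'
#' Applies the raw-EF aggregation to the normalized indicators of all
#' valid ecoregions, min-scales the resulting set, and joins the identity
#' attributes (`eco_name`, `biome_name`) from the ecoregion layer.
#' Invalid ecoregions (any indicator missing) are absent from the result.
#'
#' @param tab normalized indicator table from [normalizeIndicators()].
#' @param regions an [EcoregionSet-class] supplying identity attributes.
#' @param ref_min optional external reference minimum for the scaling
#'   (see [scaleByMin()]).
#' @return data.frame with columns `eco_id`, `eco_name`, `biome_name`,
#'   `ef_raw`, `ef`.
#' @examples
#' w <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 5, seed = 7)
#' ind <- assembleIndicators(ecoregions(w), w@landcover, w@wetlands,
#'                           w@roadless, w@gep)
#' ef <- computeEFTable(normalizeIndicators(ind), ecoregions(w))
#' min(ef$ef)  # exactly 1
#' @export
computeEFTable <- function(tab, regions, ref_min = NULL) {
  stopifnot(is(regions, "EcoregionSet"))
  need <- c("eco_id", "sgf", "sw", "gep", "sra", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("indicator table not normalized: missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  keep <- tab[tab$valid, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no valid ecoregions: nothing to compute an EF for", call. = FALSE)
  raw <- efRaw(keep$sgf, keep$sw, keep$gep, keep$sra)
  rd <- featureData(regions)
  idx <- match(keep$eco_id, rd$eco_id)
  if (anyNA(idx))
    stop("indicator rows without matching ecoregion: ",
         paste(keep$eco_id[is.na(idx)], collapse = ", "), call. = FALSE)
  data.frame(eco_id = keep$eco_id,
             eco_name = rd$eco_name[idx],
             biome_name = rd$biome_name[idx],
             ef_raw = raw,
             ef = scaleByMin(raw, ref_min = ref_min),
             stringsAsFactors = FALSE)
}
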