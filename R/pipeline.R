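#' Build and validate a pipeline configuration
#'
#' Collects the input paths and options of a full Ecoregion Factor run and
#' validates them up front: every referenced path must exist and
#' `ref_min`, if given, must be positive.  Failing fast here means no
#' stage starts on a broken configuration.
#'
#' @param ecoregions,countries paths to WKT-CSV polygon layers.
#' @param landcover path to the categorical land-cover ASCII grid.
#' @param wetlands,roadless paths to WKT-CSV coverage layers.
#' @param gep character vector of four paths to the per-taxon
#'   extinction-probability ASCII grids (amphibians, birds, reptiles,
#'   mammals).
#' @param richness optional path to a species-richness ASCII grid; when
#'   `NULL` the validation stage is skipped.
#' @param out_dir output directory for all pipeline products.
#' @param planar logical; `TRUE` computes areas in planar CRS units
#'   (exact for synthetic worlds), `FALSE` as spherical surface areas.
#' @param ref_min optional external reference minimum for EF scaling.
#' @param classes land-cover codes counted as grassland or forest.
#' @return A `PipelineConfig` (named list, class-tagged).
#' @export
pipelineConfig <- function(ecoregions, countries, landcover, wetlands,
                           roadless, gep, richness = NULL, out_dir,
                           planar = TRUE, ref_min = NULL,
                           classes = c(1, 2)) {
  paths <- c(ecoregions = ecoregions, countries = countries,
             landcover = landcover, wetlands = wetlands,
             roadless = roadless,
             stats::setNames(gep, paste0("gep", seq_along(gep))))
  if (!is.null(richness)) paths <- c(paths, richness = richness)
  if (length(gep) != 4L)
    stop("gep must list four raster paths", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) do not exist: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  if (!is.null(ref_min) && (!is.finite(ref_min) || ref_min <= 0))
    stop("ref_min must be positive", call. = FALSE)
  structure(list(ecoregions = ecoregions, countries = countries,
                 landcover = landcover, wetlands = wetlands,
                 roadless = roadless, gep = gep, richness = richness,
                 out_dir = out_dir, planar = planar, ref_min = ref_min,
                 classes = classes),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full Ecoregion Factor pipeline from files
#'
#' Executes all stages in order — indicator extraction, normalization,
#' EF aggregation and min-scaling, area-weighted country aggregation,
#' Spearman validation against a richness layer (when configured) — and
#' writes the products into `out_dir`: the indicator, EF and country
#' tables as CSV, the two-worksheet workbook, the two EF vector layers
#' and a JSON validation report.  Per-stage record counts (retained and
#' dropped ecoregions, countries with an EF) are logged as messages.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return Invisibly, a list with `indicators`, `ef_table`,
#'   `country_table`, `correlation` (or `NULL`) and `files` (named vector
#'   of written paths).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    stop("config must come from pipelineConfig()", call. = FALSE)
  taxa <- c("amphibians", "birds", "reptiles", "mammals")
  inputs <- .stage("read", list(
    ecoregions = readVectorCSV(config$ecoregions, class = "EcoregionSet"),
    countries = readVectorCSV(config$countries, class = "CountrySet"),
    landcover = readRasterASC(config$landcover),
    wetlands = readVectorCSV(config$wetlands),
    roadless = readVectorCSV(config$roadless),
    gep = stats::setNames(lapply(config$gep, readRasterASC), taxa),
    richness = if (!is.null(config$richness))
      readRasterASC(config$richness)))
  .runPipelineCore(inputs, config$out_dir, planar = config$planar,
                   ref_min = config$ref_min, classes = config$classes)
}

#' Run the pipeline on an in-memory synthetic world
#'
#' Same stages and products as [runPipeline()], but starting from a
#' [SyntheticWorld-class] instead of files; with `out_dir = NULL` nothing
#' is written and only the in-memory results are returned.
#'
#' @param world a [SyntheticWorld-class].
#' @param out_dir output directory, or `NULL` for in-memory only.
#' @inheritParams pipelineConfig
#' @return As [runPipeline()].
#' @examples
#' w <- simulateWorld(3, 3, n_countries = 2, pixels_per_cell = 5, seed = 7)
#' res <- runWorldPipeline(w)
#' res$correlation
#' @export
runWorldPipeline <- function(world, out_dir = NULL, planar = TRUE,
                             ref_min = NULL, classes = c(1, 2)) {
  stopifnot(is(world, "SyntheticWorld"))
  inputs <- list(ecoregions = world@ecoregions, countries = world@countries,
                 landcover = world@landcover, wetlands = world@wetlands,
                 roadless = world@roadless, gep = world@gep,
                 richness = world@richness)
  .runPipelineCore(inputs, out_dir, planar = planar, ref_min = ref_min,
                   classes = classes)
}

.runPipelineCore <- function(inputs, out_dir, planar, ref_min, classes) {
  ind <- .stage("indicators",
    assembleIndicators(inputs$ecoregions, inputs$landcover,
                       inputs$wetlands, inputs$roadless, inputs$gep,
                       classes = classes, planar = planar))
  n_total <- nrow(ind)
  n_valid <- sum(ind$valid)
  message("indicators: ", n_valid, " retained / ",
          n_total - n_valid, " dropped / ", n_total, " total ecoregions")
  norm <- .stage("normalize", normalizeIndicators(ind))
  ef <- .stage("ef", computeEFTable(norm, inputs$ecoregions,
                                    ref_min = ref_min))
  wts <- .stage("countries",
    intersectionWeights(inputs$ecoregions, inputs$countries,
                        planar = planar))
  cty <- .stage("countries", countryEF(wts, ef, inputs$countries))
  message("countries: ", nrow(cty), " of ", length(inputs$countries),
          " with an EF value")
  corr <- NULL
  if (!is.null(inputs$richness)) {
    corr <- .stage("validate",
      validateEF(ef, inputs$richness, inputs$ecoregions))
    message(sprintf("validation: Spearman rho = %.4f (n = %d)",
                    corr@rho, corr@n))
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(indicators = file.path(out_dir, "indicators.csv"),
               ef_table = file.path(out_dir, "ef_table.csv"),
               country_table = file.path(out_dir, "country_table.csv"),
               workbook = file.path(out_dir, "ef_workbook.xml"))
    .stage("write", {
      writeTableCSV(norm, files[["indicators"]])
      writeTableCSV(ef, files[["ef_table"]])
      writeTableCSV(cty, files[["country_table"]])
      writeWorkbook(ef, cty, files[["workbook"]])
      geo <- writeGeoLayers(ef, cty, inputs$ecoregions, inputs$countries,
                            out_dir)
      files <- c(files, ef_ecoregions = geo[1L], ef_countries = geo[2L])
      if (!is.null(corr)) {
        vp <- file.path(out_dir, "validation.json")
        jsonlite::write_json(list(rho = corr@rho, p_value = corr@p.value,
                                  n = corr@n),
                             vp, auto_unbox = TRUE, digits = NA)
        files <- c(files, validation = vp)
      }
    })
  }
  invisible(list(indicators = norm, ef_table = ef, country_table = cty,
                 correlation = corr, files = files))
}
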