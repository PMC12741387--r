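## Readers/writers for the deliverable and interchange formats.  All
## on-disk formats are plain text: vector layers as CSV with a WKT
## geometry column, rasters as ESRI ASCII grid (.asc), inter-stage tables
## as CSV, the two-worksheet deliverable as SpreadsheetML 2003 XML and the
## validation report as JSON.  Numeric fields are serialized with 17
## significant digits so round trips preserve doubles exactly.

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.wktFromRects <- function(m) {
  ring <- function(r) sprintf("((%s %s, %s %s, %s %s, %s %s, %s %s))",
    .fmtNum(r[1L]), .fmtNum(r[2L]), .fmtNum(r[3L]), .fmtNum(r[2L]),
    .fmtNum(r[3L]), .fmtNum(r[4L]), .fmtNum(r[1L]), .fmtNum(r[4L]),
    .fmtNum(r[1L]), .fmtNum(r[2L]))
  rings <- apply(m, 1L, ring)
  if (nrow(m) == 1L) paste0("POLYGON ", rings)
  else paste0("MULTIPOLYGON (", paste(rings, collapse = ", "), ")")
}

## Parse POLYGON/MULTIPOLYGON WKT whose rings are axis-aligned rectangles
## (the only geometry this package produces).
.rectsFromWKT <- function(s) {
  rings <- regmatches(s, gregexpr("\\(([^()]+)\\)", s))[[1L]]
  if (!length(rings))
    stop("cannot parse WKT geometry: ", substr(s, 1L, 40L), call. = FALSE)
  rects <- t(vapply(rings, function(ring) {
    body <- gsub("[()]", "", ring)
    pts <- strsplit(trimws(strsplit(body, ",")[[1L]]), "[[:space:]]+")
    xy <- do.call(rbind, lapply(pts, as.numeric))
    if (nrow(xy) < 4L || anyNA(xy))
      stop("malformed WKT ring", call. = FALSE)
    ux <- unique(xy[, 1L]); uy <- unique(xy[, 2L])
    if (length(ux) != 2L || length(uy) != 2L)
      stop("WKT ring is not an axis-aligned rectangle", call. = FALSE)
    c(min(ux), min(uy), max(ux), max(uy))
  }, numeric(4)))
  .asRects(rects)
}

#' Write / read a rectangle-polygon layer as WKT CSV
#'
#' The layer's attribute table is written as CSV with an added `wkt`
#' column holding the feature geometry as POLYGON/MULTIPOLYGON well-known
#' text — a plain-text vector format loadable by standard GIS tools.
#' Coordinates are serialized with 17 significant digits, so a write/read
#' round trip reproduces the layer exactly.
#'
#' @param layer a [RectLayer-class] (or subclass).
#' @param path output/input file path.
#' @param class S4 class to instantiate on read (`"RectLayer"`,
#'   `"EcoregionSet"` or `"CountrySet"`).
#' @param crs CRS label to attach on read.
#' @return `writeVectorCSV()` the path, invisibly; `readVectorCSV()` the
#'   reconstructed layer.
#' @export
writeVectorCSV <- function(layer, path) {
  stopifnot(is(layer, "RectLayer"))
  df <- featureData(layer)
  df$wkt <- vapply(geometry(layer), .wktFromRects, character(1))
  .writeTableCSV(df, path)
  invisible(path)
}

#' @rdname writeVectorCSV
#' @export
readVectorCSV <- function(path, class = "RectLayer", crs = "EPSG:4326") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"wkt" %in% names(df))
    stop("no 'wkt' geometry column in ", path, call. = FALSE)
  rects <- lapply(df$wkt, .rectsFromWKT)
  df$wkt <- NULL
  rectLayer(rects, df, crs = crs, class = class)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text single-band raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from north to south).
#' Requires square cells.  Values are serialized with 17 significant
#' digits for exact round trips; `NA` cells become the nodata value.
#'
#' @param raster a [GridRaster-class] with `xres == yres`.
#' @param path output/input file path.
#' @param crs CRS label to attach on read.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `writeRasterASC()` the path, invisibly; `readRasterASC()` a
#'   [GridRaster-class].
#' @export
writeRasterASC <- function(raster, path, nodata = -9999) {
  stopifnot(is(raster, "GridRaster"))
  if (!isTRUE(all.equal(raster@xres, raster@yres)))
    stop("ASCII grid requires square cells (xres == yres)", call. = FALSE)
  v <- raster@values
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", .fmtNum(raster@xmin)),
           paste("yllcorner", .fmtNum(raster@ymax - nrow(v) * raster@yres)),
           paste("cellsize", .fmtNum(raster@xres)),
           paste("NODATA_value", .fmtNum(nodata)))
  body <- apply(v, 1L, function(row) {
    row[is.na(row)] <- nodata
    paste(.fmtNum(row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeRasterASC
#' @export
readRasterASC <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  gridRaster(v, xmin = hdr$xllcorner,
             ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
             xres = hdr$cellsize, yres = hdr$cellsize, crs = crs)
}

## Deterministic CSV writer: doubles at 17 significant digits, stable
## column order, so reruns with identical inputs are byte-identical.
.writeTableCSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write / read the inter-stage tables as CSV
#'
#' CSV is the package's interchange format between pipeline stages
#' (indicator table, EF table, country table): inspectable, diffable and
#' byte-stable across reruns.  Doubles are serialized with 17 significant
#' digits.
#'
#' @param tab a data.frame.
#' @param path file path.
#' @return `writeTableCSV()` the path invisibly; `readTableCSV()` the
#'   data.frame.
#' @export
writeTableCSV <- function(tab, path) .writeTableCSV(tab, path)

#' @rdname writeTableCSV
#' @export
readTableCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.sheetXML <- function(name, df) {
  cell <- function(val, num) {
    if (num) sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
                     .fmtNum(val))
    else sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
                 .xmlEscape(as.character(val)))
  }
  isnum <- vapply(df, is.numeric, logical(1))
  head_row <- paste0("<Row>",
    paste(vapply(names(df), cell, character(1), num = FALSE),
          collapse = ""), "</Row>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j)
      cell(df[[j]][i], isnum[j]), character(1))
    paste0("<Row>", paste(cells, collapse = ""), "</Row>")
  }, character(1))
  c(sprintf('<Worksheet ss:Name="%s"><Table>', .xmlEscape(name)),
    head_row, body, "</Table></Worksheet>")
}

#' Write the two-worksheet EF deliverable workbook
#'
#' Emits the deliverable spreadsheet as SpreadsheetML 2003 XML (a
#' plain-text, Excel-openable workbook format) with exactly two
#' worksheets: *Ecoregion level* with columns `ECO_NAME`, `BIOME_NAME`,
#' `ECO_ID`, `EF` and *Country level* with columns `COUNTRY`, `ISO_CC`,
#' `EF`.  Worksheet and column names are a fixed contract — downstream
#' assessment tools key on them.
#'
#' @param ef_table non-empty data.frame from [computeEFTable()].
#' @param country_table non-empty data.frame from [countryEF()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeWorkbook <- function(ef_table, country_table, path) {
  if (nrow(ef_table) == 0L || nrow(country_table) == 0L)
    stop("both worksheets must be non-empty", call. = FALSE)
  eco <- data.frame(ECO_NAME = ef_table$eco_name,
                    BIOME_NAME = ef_table$biome_name,
                    ECO_ID = as.numeric(ef_table$eco_id),
                    EF = ef_table$ef, stringsAsFactors = FALSE)
  cty <- data.frame(COUNTRY = country_table$country,
                    ISO_CC = country_table$iso_cc,
                    EF = country_table$ef, stringsAsFactors = FALSE)
  lines <- c('<?xml version="1.0"?>',
    '<?mso-application progid="Excel.Sheet"?>',
    paste0('<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
           ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">'),
    .sheetXML("Ecoregion level", eco),
    .sheetXML("Country level", cty),
    "</Workbook>")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a workbook written by [writeWorkbook()]
#'
#' @param path workbook file path.
#' @return Named list of data.frames, one per worksheet, in file order.
#' @export
readWorkbook <- function(path) {
  doc <- xml2::read_xml(path)
  sheets <- xml2::xml_find_all(doc, ".//*[local-name()='Worksheet']")
  out <- list()
  for (ws in sheets) {
    name <- xml2::xml_attr(ws, "Name")
    rows <- xml2::xml_find_all(ws, ".//*[local-name()='Row']")
    header <- xml2::xml_text(
      xml2::xml_find_all(rows[[1L]], ".//*[local-name()='Data']"))
    cols <- lapply(seq_along(header), function(j) character(0))
    types <- rep("String", length(header))
    for (i in seq_along(rows)[-1L]) {
      data <- xml2::xml_find_all(rows[[i]], ".//*[local-name()='Data']")
      for (j in seq_along(header)) {
        cols[[j]] <- c(cols[[j]], xml2::xml_text(data[[j]]))
        types[j] <- xml2::xml_attr(data[[j]], "Type")
      }
    }
    df <- as.data.frame(stats::setNames(cols, header),
                        stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(header))
      if (types[j] == "Number") df[[j]] <- as.numeric(df[[j]])
    out[[name]] <- df
  }
  out
}

#' Write the EF vector deliverables
#'
#' Joins the per-ecoregion and per-country EF values onto their polygon
#' layers and writes two WKT-CSV vector files (`ef_ecoregions.csv`,
#' `ef_countries.csv`) with the deliverable attribute schemas
#' (`ECO_NAME`, `BIOME_NAME`, `ECO_ID`, `EF` / `COUNTRY`, `ISO_CC`, `EF`)
#' in geographic coordinates.  Table rows without a matching geometry are
#' an error listing the orphans.
#'
#' @param ef_table data.frame from [computeEFTable()].
#' @param country_table data.frame from [countryEF()].
#' @param ecoregions an [EcoregionSet-class].
#' @param countries a [CountrySet-class].
#' @param outdir output directory (created if missing).
#' @return Character vector of the two paths, invisibly.
#' @export
writeGeoLayers <- function(ef_table, country_table, ecoregions, countries,
                           outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ei <- match(ef_table$eco_id, featureData(ecoregions)$eco_id)
  if (anyNA(ei))
    stop("EF rows without matching ecoregion geometry: ",
         paste(ef_table$eco_id[is.na(ei)], collapse = ", "), call. = FALSE)
  ci <- match(country_table$iso_cc, featureData(countries)$iso_cc)
  if (anyNA(ci))
    stop("country rows without matching geometry: ",
         paste(country_table$iso_cc[is.na(ci)], collapse = ", "),
         call. = FALSE)
  eco_layer <- rectLayer(geometry(ecoregions)[ei],
    data.frame(ECO_NAME = ef_table$eco_name,
               BIOME_NAME = ef_table$biome_name,
               ECO_ID = ef_table$eco_id, EF = ef_table$ef,
               stringsAsFactors = FALSE),
    crs = crsName(ecoregions))
  cty_layer <- rectLayer(geometry(countries)[ci],
    data.frame(COUNTRY = country_table$country,
               ISO_CC = country_table$iso_cc, EF = country_table$ef,
               stringsAsFactors = FALSE),
    crs = crsName(countries))
  p1 <- file.path(outdir, "ef_ecoregions.csv")
  p2 <- file.path(outdir, "ef_countries.csv")
  writeVectorCSV(eco_layer, p1)
  writeVectorCSV(cty_layer, p2)
  invisible(c(p1, p2))
}

#' Write / read a synthetic world directory
#'
#' Serializes every layer of a [SyntheticWorld-class] into a directory of
#' plain-text files: WKT-CSV vector layers, ASCII-grid rasters, the
#' ground-truth table as CSV and a key-value `manifest.txt` recording the
#' seed and grid shape.  `readWorld()` reconstructs the world exactly.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir target/source directory.
#' @return `writeWorld()` the directory invisibly; `readWorld()` a
#'   [SyntheticWorld-class].
#' @export
writeWorld <- function(world, dir) {
  stopifnot(is(world, "SyntheticWorld"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVectorCSV(world@ecoregions, file.path(dir, "ecoregions.csv"))
  writeVectorCSV(world@countries, file.path(dir, "countries.csv"))
  writeVectorCSV(world@wetlands, file.path(dir, "wetlands.csv"))
  writeVectorCSV(world@roadless, file.path(dir, "roadless.csv"))
  writeRasterASC(world@landcover, file.path(dir, "landcover.asc"))
  for (t in names(world@gep))
    writeRasterASC(world@gep[[t]], file.path(dir, paste0("gep_", t, ".asc")))
  writeRasterASC(world@richness, file.path(dir, "richness.asc"))
  .writeTableCSV(world@truth, file.path(dir, "truth.csv"))
  writeLines(c(paste0("seed=", world@seed),
               paste0("n_ecoregions=", length(world@ecoregions)),
               paste0("n_countries=", length(world@countries)),
               paste0("crs=", crsName(world@ecoregions))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname writeWorld
#' @export
readWorld <- function(dir) {
  man <- readConfig(file.path(dir, "manifest.txt"))
  crs <- if (!is.null(man$crs)) man$crs else "EPSG:4326"
  taxa <- c("amphibians", "birds", "reptiles", "mammals")
  gep <- stats::setNames(lapply(taxa, function(t)
    readRasterASC(file.path(dir, paste0("gep_", t, ".asc")), crs = crs)),
    taxa)
  new("SyntheticWorld",
      ecoregions = readVectorCSV(file.path(dir, "ecoregions.csv"),
                                 class = "EcoregionSet", crs = crs),
      countries = readVectorCSV(file.path(dir, "countries.csv"),
                                class = "CountrySet", crs = crs),
      landcover = readRasterASC(file.path(dir, "landcover.asc"), crs = crs),
      wetlands = readVectorCSV(file.path(dir, "wetlands.csv"), crs = crs),
      roadless = readVectorCSV(file.path(dir, "roadless.csv"), crs = crs),
      gep = gep,
      richness = readRasterASC(file.path(dir, "richness.asc"), crs = crs),
      truth = utils::read.csv(file.path(dir, "truth.csv")),
      seed = as.integer(man$seed))
}

#' Read a key-value configuration file
#'
#' Parses `key=value` lines (blank lines and `#` comments ignored) into a
#' named list.
#'
#' @param path file path.
#' @return Named list of character values.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x)
    trimws(paste(x[-1L], collapse = "="))),
    vapply(kv, function(x) trimws(x[1L]), character(1)))
}
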