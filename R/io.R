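# Plain-text raster and table I/O. Rasters travel as ESRI ASCII grids
# (.asc) — one per band plus an integer QA grid — with a JSON sidecar
# carrying the date, band list, CRS and pixel size. Tables are CSV with
# the published dataset's column layout.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric matrix (row 1 = northernmost scan line).
#' @param path Output file path.
#' @param transform Affine transform `c(x0, y0, cell)` (north-west outer
#'   corner and cell size), see [scene_stack()].
#' @param nodata NODATA value written for `NA` cells (default -9999).
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(m, path, transform = c(0, nrow(m), 1),
                      nodata = -9999, digits = 10) {
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(transform[1], digits = 15)),
    paste("yllcorner", format(transform[2] - nr * transform[3],
                              digits = 15)),
    paste("cellsize", format(transform[3], digits = 15)),
    paste("NODATA_value", nodata))
  m2 <- m
  m2[!is.finite(m2)] <- nodata
  rows <- apply(m2, 1, function(r)
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_asc()] (or any ESRI ASCII grid).
#' @return A numeric matrix with attribute `transform = c(x0, y0, cell)`;
#'   NODATA cells are `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("grid has ", length(vals), " cells, expected ", nr * nc)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cell <- hdr$cellsize
  attr(m, "transform") <- c(hdr$xllcorner, hdr$yllcorner + nr * cell, cell)
  m
}

#' Write a scene stack to a directory
#'
#' One ASCII grid per band (`band_<name>.asc`), an integer QA grid
#' (`qa.asc`) and a `meta.json` sidecar (date, band names, CRS, pixel
#' size).
#'
#' @param scene A [scene_stack].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$bands))
    write_asc(scene$bands[[nm]], file.path(dir, paste0("band_", nm, ".asc")),
              transform = scene$transform)
  write_asc(scene$qa, file.path(dir, "qa.asc"),
            transform = scene$transform, digits = 1)
  meta <- list(date = format(scene$date), bands = names(scene$bands),
               crs = scene$crs, pixel_size_m = scene$pixel_size_m,
               transform = scene$transform)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene stack from a directory
#'
#' Inverse of [write_scene()]. Band names may be re-mapped to the
#' canonical `red/green/blue/nir/swir1640` set through `band_map`.
#'
#' @param dir Directory written by [write_scene()].
#' @param band_map Optional named character vector mapping canonical
#'   names to stored band names, e.g. `c(red = "b1")`.
#' @return A [scene_stack].
#' @export
read_scene <- function(dir, band_map = NULL) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a scene directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stored <- meta$bands
  wanted <- if (is.null(band_map)) stats::setNames(stored, stored)
            else band_map
  missing <- setdiff(unname(wanted), stored)
  if (length(missing))
    stop("scene is missing band(s): ", paste(missing, collapse = ", "))
  bands <- list()
  tr <- NULL
  for (i in seq_along(wanted)) {
    m <- read_asc(file.path(dir, paste0("band_", wanted[[i]], ".asc")))
    tr <- attr(m, "transform")
    attr(m, "transform") <- NULL
    bands[[names(wanted)[i]]] <- m
  }
  qa_path <- file.path(dir, "qa.asc")
  if (!file.exists(qa_path)) stop("scene has no QA band: ", dir)
  qa <- read_asc(qa_path)
  attr(qa, "transform") <- NULL
  qa[is.na(qa)] <- 0
  scene_stack(as.Date(meta$date), bands, qa,
              transform = as.numeric(meta$transform), crs = meta$crs,
              pixel_size_m = meta$pixel_size_m)
}

# ---- dataset tables -------------------------------------------------------

.LAKE_INFO_COLS <- c("Lake_id", "Lake_name", "Lon", "Lat", "Lake_area",
                     "Freezing", "Country/Region", "Continent")

#' Assemble the lake inventory table
#'
#' @param lakes List of `normal_water_mask` objects.
#' @param lake_names,countries,continents Optional character vectors
#'   (recycled empty when not supplied).
#' @return Data frame with the published `lake_info` column layout.
#' @export
lake_info_table <- function(lakes, lake_names = NULL, countries = NULL,
                            continents = NULL) {
  n <- length(lakes)
  blank <- function(v) if (is.null(v)) rep("", n) else v
  df <- data.frame(
    Lake_id = vapply(lakes, function(l) l$lake_id, character(1)),
    Lake_name = blank(lake_names),
    Lon = vapply(lakes, function(l) l$centroid_x, numeric(1)),
    Lat = vapply(lakes, function(l) l$centroid_y, numeric(1)),
    Lake_area = vapply(lakes, function(l) l$area_km2, numeric(1)),
    Freezing = ifelse(vapply(lakes, function(l) l$freezing, logical(1)),
                      "Yes", "No"),
    check.names = FALSE)
  df[["Country/Region"]] <- blank(countries)
  df[["Continent"]] <- blank(continents)
  df[order(df$Lake_id), , drop = FALSE]
}

#' Write the dataset tables
#'
#' Writes `lake_info.csv`, `raw_monthly_FUI.csv`, `filled_monthly_FUI.csv`
#' and `yearly_FUI.csv` in the published layout: monthly tables have one
#' row per lake and one column per month (`YYYY-MM`), the yearly table
#' one column per year; rows are ordered by `Lake_id`; non-finite FUI
#' cells serialize as empty fields.
#'
#' @param lake_info Data frame from [lake_info_table()].
#' @param monthly_raw,monthly_filled Data frames: `Lake_id` plus one
#'   numeric column per month.
#' @param yearly Data frame: `Lake_id` plus one numeric column per year.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(lake_info, monthly_raw, monthly_filled, yearly,
                          outdir) {
  missing <- setdiff(.LAKE_INFO_COLS, names(lake_info))
  if (length(missing))
    stop("lake_info violates the schema; missing column(s): ",
         paste(missing, collapse = ", "))
  for (tb in list(monthly_raw, monthly_filled, yearly))
    if (!"Lake_id" %in% names(tb))
      stop("monthly/yearly tables must carry a Lake_id column")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    df <- df[order(df$Lake_id), , drop = FALSE]
    utils::write.csv(df, file.path(outdir, f), row.names = FALSE,
                     na = "")
  }
  wr(lake_info, "lake_info.csv")
  wr(monthly_raw, "raw_monthly_FUI.csv")
  wr(monthly_filled, "filled_monthly_FUI.csv")
  wr(yearly, "yearly_FUI.csv")
  invisible(outdir)
}

# ---- configuration --------------------------------------------------------

#' Pipeline configuration
#'
#' Single source of the pipeline's constants. All defaults are the
#' published workflow's printed values; nothing is hard-coded at call
#' sites.
#'
#' @param t0,t1 1640 nm threshold window edges (0.04, 0.12).
#' @param bin_width Histogram bin width (0.002).
#' @param occurrence Normal-mask occurrence threshold (0.30).
#' @param coverage Monthly coverage threshold (0.30).
#' @param shallow_blue Optically-shallow blue ceiling (0.06).
#' @param k_temporal,k_spatial Outlier window half-widths (3, 1.5).
#' @param min_months_nonfreezing,min_months_freezing Per-year validity
#'   minima (6, 3).
#' @param apply_delta Apply the band-setting deviation correction to
#'   satellite scenes (`TRUE`).
#' @param drop_lake_on_any_bad_year Exclude a lake entirely if any year
#'   fails its months rule (`TRUE`).
#' @param min_area_km2 Minimum lake area (25).
#' @param nir_swir,visible Band-name sets for the correction and
#'   colorimetry.
#' @param seed Integer seed for any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(t0 = 0.04, t1 = 0.12, bin_width = 0.002,
                            occurrence = 0.30, coverage = 0.30,
                            shallow_blue = 0.06,
                            k_temporal = 3, k_spatial = 1.5,
                            min_months_nonfreezing = 6,
                            min_months_freezing = 3,
                            apply_delta = TRUE,
                            drop_lake_on_any_bad_year = TRUE,
                            min_area_km2 = 25,
                            nir_swir = c("nir", "swir1640"),
                            visible = c("red", "green", "blue"),
                            seed = 1L) {
  cfg <- list(t0 = t0, t1 = t1, bin_width = bin_width,
              occurrence = occurrence, coverage = coverage,
              shallow_blue = shallow_blue, k_temporal = k_temporal,
              k_spatial = k_spatial,
              min_months_nonfreezing = min_months_nonfreezing,
              min_months_freezing = min_months_freezing,
              apply_delta = isTRUE(apply_delta),
              drop_lake_on_any_bad_year = isTRUE(drop_lake_on_any_bad_year),
              min_area_km2 = min_area_km2,
              nir_swir = nir_swir, visible = visible,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A list of configuration values.
#' @return Invisibly `TRUE`; stops with the offending field on violation.
#' @export
validate_config <- function(cfg) {
  if (!(cfg$t0 < cfg$t1)) stop("config error: t0 must be < t1")
  for (f in c("occurrence", "coverage"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config error: ", f, " must be in (0, 1)")
  for (f in c("k_temporal", "k_spatial"))
    if (cfg[[f]] <= 0) stop("config error: ", f, " must be > 0")
  if (cfg$bin_width <= 0) stop("config error: bin_width must be > 0")
  if (!length(cfg$nir_swir)) stop("config error: nir_swir is empty")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as JSON
#'
#' Round-trips through serialization without loss.
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
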