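# End-to-end composition: scenes -> water-leaving correction -> adaptive
# lake extraction -> normal masks -> per-date FUI rasters -> monthly and
# yearly per-lake series -> dataset tables, with per-stage accounting.

.month_key <- function(date) format(date, "%Y-%m")

#' Run the full scene-to-dataset pipeline
#'
#' Executes every stage on a list of scenes sharing one grid: corrects
#' water-leaving reflectance, finds candidate lakes from QA inland-water
#' occurrence, refines each lake per date with its adaptive 1640 nm
#' threshold, builds the occurrence-based normal water masks, retrieves
#' per-date FUI rasters, aggregates them into quality-controlled monthly
#' and yearly per-lake series (outlier filters, coverage and validity
#' rules, gap filling), fits yearly trends where at least three years
#' are available, and optionally writes the dataset tables.
#'
#' Deterministic for a fixed scene list and configuration.
#'
#' @param scenes List of [scene_stack] objects (all the same grid), or a
#'   directory containing scene subdirectories written by [write_scene()].
#' @param config A [pipeline_config()].
#' @param freezing Per-lake freezing status: `NULL` (all non-freezing), a
#'   logical vector indexed like the extracted lakes, or a data frame
#'   with columns `x`, `y`, `freezing` matched to the nearest lake
#'   centroid.
#' @param outdir Optional output directory for the dataset CSVs.
#' @param verbose Emit per-lake diagnostics.
#' @return A list: `lakes` (list of `normal_water_mask`), `lake_info`,
#'   `monthly` (long data frame), `monthly_raw`, `monthly_filled`,
#'   `yearly` (wide tables), `trends`, `fui_rasters` (per date, masked),
#'   `log` (data frame of per-stage record counts).
#' @export
run_pipeline <- function(scenes, config = pipeline_config(),
                         freezing = NULL, outdir = NULL,
                         verbose = FALSE) {
  validate_config(config)
  if (is.character(scenes)) {
    dirs <- list.dirs(scenes, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
    if (!length(dirs)) stop("stage read_scenes: no scenes found in ", scenes)
    scenes <- lapply(dirs, read_scene)
  }
  if (!length(scenes)) stop("stage read_scenes: empty scene list")
  dates <- as.Date(vapply(scenes, function(s) format(s$date), character(1)))
  ord <- order(dates)
  scenes <- scenes[ord]; dates <- dates[ord]
  n_dates <- length(dates)
  say <- function(...) if (verbose) message(...)
  logs <- list()
  log_add <- function(stage, detail, n) {
    logs[[length(logs) + 1L]] <<- data.frame(stage = stage,
                                             detail = detail, n = n)
  }

  # stage 1: water-leaving correction
  corrected <- lapply(scenes, correct_water_leaving,
                      nir_swir = config$nir_swir,
                      visible = config$visible)
  log_add("correct", "pixels clamped to zero reflectance",
          sum(vapply(corrected, function(s) sum(s$clamped), numeric(1))))

  # stage 2: candidate lakes from QA inland-water occurrence
  dims <- dim(scenes[[1]]$bands[[1]])
  water_n <- matrix(0, dims[1], dims[2])
  obs_n <- matrix(0, dims[1], dims[2])
  for (s in scenes) {
    obs <- !qa_blocked(s$qa)
    water_n <- water_n + (initial_water_mask(s) & obs)
    obs_n <- obs_n + obs
  }
  candidate <- ifelse(obs_n > 0, water_n / obs_n, 0) > config$occurrence
  regions <- connected_components(candidate,
                                  pixel_size_m = scenes[[1]]$pixel_size_m,
                                  min_area_km2 = config$min_area_km2)
  if (!length(regions))
    stop("stage extract: no lake above ", config$min_area_km2, " km^2")
  regions <- lapply(regions, build_buffer)
  log_add("extract", "candidate lakes above the area floor",
          length(regions))

  # stage 3: per-lake per-date refinement and normal masks
  lakes <- list()
  refined_by_lake <- list()
  for (li in seq_along(regions)) {
    reg <- regions[[li]]
    refined <- vector("list", n_dates)
    observable <- vector("list", n_dates)
    unobserved <- 0L
    for (di in seq_len(n_dates)) {
      reg_d <- reg
      reg_d$threshold <- NA_real_   # adaptive per date
      reg_d <- refine_lake(scenes[[di]], reg_d,
                           t0 = config$t0, t1 = config$t1,
                           bin_width = config$bin_width,
                           shallow_blue = config$shallow_blue,
                           corrected = corrected[[di]])
      refined[[di]] <- reg_d$refined_mask
      observable[[di]] <- !qa_blocked(scenes[[di]]$qa)
      if (!reg_d$observed) unobserved <- unobserved + 1L
    }
    sc1 <- scenes[[1]]
    nm <- normal_water_mask(refined, observable,
                            occurrence_min = config$occurrence,
                            transform = sc1$transform,
                            pixel_size_m = sc1$pixel_size_m,
                            lake_id = reg$lake_id)
    lakes[[li]] <- nm
    refined_by_lake[[li]] <- refined
    say("lake ", nm$lake_id, ": area ", nm$area_km2, " km^2, ",
        unobserved, "/", n_dates, " unobserved composites")
    log_add("refine", paste0(nm$lake_id, " unobserved composites"),
            unobserved)
  }
  drop_empty <- vapply(lakes, function(l) !any(l$mask), logical(1))
  if (any(drop_empty)) {
    log_add("normal_mask", "lakes dropped (empty normal mask)",
            sum(drop_empty))
    lakes <- lakes[!drop_empty]
    refined_by_lake <- refined_by_lake[!drop_empty]
  }
  if (!length(lakes)) stop("stage normal_mask: no lake survived")

  # freezing status
  nlk <- length(lakes)
  frz <- rep(FALSE, nlk)
  if (is.logical(freezing)) frz <- rep_len(freezing, nlk)
  if (is.data.frame(freezing)) {
    for (li in seq_len(nlk)) {
      d2 <- (freezing$x - lakes[[li]]$centroid_x)^2 +
        (freezing$y - lakes[[li]]$centroid_y)^2
      frz[li] <- isTRUE(freezing$freezing[which.min(d2)])
    }
  }
  for (li in seq_len(nlk)) lakes[[li]]$freezing <- frz[li]

  # stage 4: per-date FUI rasters (masked to each date's refined water)
  fui_rasters <- vector("list", n_dates)
  names(fui_rasters) <- format(dates)
  for (di in seq_len(n_dates)) {
    valid <- matrix(FALSE, dims[1], dims[2])
    for (li in seq_len(nlk))
      valid <- valid | (refined_by_lake[[li]][[di]] & lakes[[li]]$mask)
    if (!is.null(corrected[[di]]$invalid_rgb))
      valid <- valid & !corrected[[di]]$invalid_rgb
    fui_rasters[[di]] <- fui_image(corrected[[di]], valid,
                                   apply_delta = config$apply_delta,
                                   bands = config$visible)
  }
  log_add("fui", "valid FUI pixels over all composites",
          sum(vapply(fui_rasters, function(r) sum(is.finite(r)),
                     numeric(1))))

  # stage 5: monthly series per lake
  mk <- .month_key(dates)
  all_months <- sort(unique(mk))
  monthly <- list()
  for (li in seq_len(nlk)) {
    lk <- lakes[[li]]
    rows <- list()
    for (mo in all_months) {
      in_m <- which(mk == mo)
      comp <- monthly_composite(fui_rasters[in_m], lk$mask,
                                k = config$k_temporal)
      rec <- spatial_mean(comp, lk$mask, k = config$k_spatial,
                          min_coverage = config$coverage)
      rec$lake_id <- lk$lake_id
      rec$year <- as.integer(substr(mo, 1, 4))
      rec$month <- as.integer(substr(mo, 6, 7))
      rows[[length(rows) + 1L]] <- rec
    }
    monthly[[li]] <- do.call(rbind, rows)
  }
  monthly <- do.call(rbind, monthly)
  log_add("monthly", "invalid lake-months (coverage rule)",
          sum(!monthly$valid))

  # stage 6: validity rules, gap filling, yearly means, trends
  kept <- list(); yearly_rows <- list(); trend_rows <- list()
  excluded <- character(0)
  for (li in seq_len(nlk)) {
    lk <- lakes[[li]]
    ser <- monthly[monthly$lake_id == lk$lake_id, ]
    vr <- apply_validity_rules(
      ser, freezing = lk$freezing,
      min_months_nonfreezing = config$min_months_nonfreezing,
      min_months_freezing = config$min_months_freezing,
      drop_lake_on_any_bad_year = config$drop_lake_on_any_bad_year)
    if (!vr$lake_included) {
      excluded <- c(excluded, lk$lake_id)
      say("lake ", lk$lake_id, " excluded: years ",
          paste(vr$bad_years, collapse = ", "), " fail the months rule")
      next
    }
    ser <- vr$series
    ser$fui[!ser$valid] <- NA_real_
    ser <- fill_gaps(ser, freezing = lk$freezing)
    kept[[length(kept) + 1L]] <- ser
    yrs <- sort(unique(ser$year))
    ym <- vapply(yrs, function(y) yearly_mean(ser, y), numeric(1))
    yearly_rows[[length(yearly_rows) + 1L]] <-
      data.frame(lake_id = lk$lake_id, year = yrs, fui_yearly = ym,
                 n_months = vapply(yrs, function(y)
                   sum(is.finite(ser$fui_filled[ser$year == y])),
                   integer(1)))
    if (sum(is.finite(ym)) >= 3) {
      tr <- annual_trend(yrs, ym)
      trend_rows[[length(trend_rows) + 1L]] <-
        data.frame(lake_id = lk$lake_id, slope = tr$slope,
                   p_value = tr$p_value,
                   significant = tr$p_value < 0.01)
    }
  }
  log_add("validity", "lakes excluded by the months rule",
          length(excluded))
  if (!length(kept))
    stop("stage validity: every lake was excluded by the months rule")
  monthly_kept <- do.call(rbind, kept)
  yearly <- do.call(rbind, yearly_rows)
  trends <- if (length(trend_rows)) do.call(rbind, trend_rows) else
    data.frame(lake_id = character(0), slope = numeric(0),
               p_value = numeric(0), significant = logical(0))
  log_add("fill", "months filled by interpolation",
          sum(monthly_kept$filled))

  # wide tables in the published layout
  kept_ids <- unique(monthly_kept$lake_id)
  wide <- function(col) {
    out <- data.frame(Lake_id = kept_ids)
    for (mo in all_months) {
      y <- as.integer(substr(mo, 1, 4)); m <- as.integer(substr(mo, 6, 7))
      out[[mo]] <- vapply(kept_ids, function(id) {
        r <- monthly_kept[monthly_kept$lake_id == id &
                            monthly_kept$year == y &
                            monthly_kept$month == m, ]
        if (nrow(r) == 1 && is.finite(r[[col]])) r[[col]] else NA_real_
      }, numeric(1))
    }
    out
  }
  monthly_raw_tab <- wide("fui")
  monthly_filled_tab <- wide("fui_filled")
  years_all <- sort(unique(yearly$year))
  yearly_tab <- data.frame(Lake_id = kept_ids)
  for (y in years_all)
    yearly_tab[[as.character(y)]] <- vapply(kept_ids, function(id) {
      r <- yearly[yearly$lake_id == id & yearly$year == y, ]
      if (nrow(r) == 1) r$fui_yearly else NA_real_
    }, numeric(1))

  info <- lake_info_table(lakes[match(kept_ids,
                                      vapply(lakes, function(l) l$lake_id,
                                             character(1)))])
  if (!is.null(outdir))
    write_dataset(info, monthly_raw_tab, monthly_filled_tab, yearly_tab,
                  outdir)

  list(lakes = lakes, lake_info = info, monthly = monthly_kept,
       monthly_all = monthly, monthly_raw = monthly_raw_tab,
       monthly_filled = monthly_filled_tab, yearly = yearly,
       yearly_table = yearly_tab, trends = trends,
       fui_rasters = fui_rasters, excluded = excluded,
       log = do.call(rbind, logs))
}
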