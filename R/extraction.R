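# Adaptive lake extraction: QA-seeded initial mask, connected components,
# 1.5x buffer zone, per-lake 1640 nm threshold from the valley of the
# bimodal histogram over the expanded area, QA/erosion/shallow-water
# refinement, and the multi-year occurrence-based normal water mask.

#' Initial rough water mask from the QA band
#'
#' True exactly where the inland-water QA bit is set and none of the
#' cloud / cloud-shadow / snow-ice bits is set.
#'
#' @param scene A [scene_stack].
#' @return Logical matrix.
#' @export
initial_water_mask <- function(scene) {
  stopifnot(inherits(scene, "scene_stack"))
  qa_flag(scene$qa, "inland_water") &
    !qa_flag(scene$qa, c("cloud", "cloud_shadow", "snow_ice"))
}

#' Connected water components above a minimum area
#'
#' Labels the mask under 8-connectivity and keeps components whose area
#' is at least `min_area_km2`. Components are ordered deterministically
#' by the row-major position of their first pixel.
#'
#' @param mask Logical matrix.
#' @param pixel_size_m Ground pixel size in metres.
#' @param min_area_km2 Minimum component area to keep (default 25).
#' @return A list of `lake_region` objects, each with fields `lake_id`
#'   (filled by the caller or defaulted to the component index),
#'   `component_mask` and `area_km2`.
#' @export
connected_components <- function(mask, pixel_size_m = 500,
                                 min_area_km2 = 25) {
  lab <- label_components(mask)
  n <- max(lab)
  px_km2 <- (pixel_size_m / 1000)^2
  out <- list()
  for (k in seq_len(n)) {
    cm <- lab == k
    area <- sum(cm) * px_km2
    if (area >= min_area_km2) {
      out[[length(out) + 1L]] <- structure(
        list(lake_id = sprintf("lake_%02d", length(out) + 1L),
             component_mask = cm, area_km2 = area,
             buffer_mask = NULL, threshold = NA_real_,
             threshold_fallback = FALSE, refined_mask = NULL),
        class = "lake_region")
    }
  }
  out
}

#' Build the expanded buffer zone around a lake component
#'
#' The component is dilated ring by ring until the expanded area (the
#' component plus its buffer) reaches `factor` times the component area;
#' the first ring crossing the target is included. A buffer truncated by
#' the grid edge proceeds with a warning.
#'
#' @param region A `lake_region` from [connected_components()].
#' @param factor Expanded-to-component area ratio target (default 1.5).
#' @return The region with `buffer_mask` set (component plus buffer).
#' @export
build_buffer <- function(region, factor = 1.5) {
  stopifnot(inherits(region, "lake_region"), factor >= 1)
  comp <- region$component_mask
  if (!any(comp)) stop("component mask is empty")
  target <- factor * sum(comp)
  buf <- comp
  while (sum(buf) < target) {
    grown <- dilate3(buf)
    if (all(grown == buf)) break   # saturated the grid
    buf <- grown
  }
  if (sum(buf) < target)
    warning("buffer truncated by the grid edge: expanded area ",
            sum(buf), " < target ", target)
  region$buffer_mask <- buf
  region
}

#' Adaptive 1640 nm threshold from the bimodal histogram valley
#'
#' Bins the SWIR reflectance sample of the expanded area and returns the
#' centre of the minimum-count bin within the threshold window
#' `[t0, t1]`; ties break toward the lower reflectance. If no bin centre
#' falls in the window, or the counts are monotone across the window (no
#' valley — the bimodality prerequisite fails), the midpoint
#' `(t0 + t1)/2` is returned with attribute `fallback = TRUE` and a
#' warning.
#'
#' @param swir_values Numeric vector of 1640 nm reflectances over the
#'   expanded area.
#' @param t0,t1 Threshold window edges (defaults 0.04 and 0.12).
#' @param bin_width Histogram bin width in reflectance (default 0.002,
#'   unsmoothed counts).
#' @return Threshold (numeric scalar) with logical attribute `fallback`.
#' @export
find_threshold <- function(swir_values, t0 = 0.04, t1 = 0.12,
                           bin_width = 0.002) {
  stopifnot(t0 < t1, bin_width > 0)
  v <- swir_values[is.finite(swir_values)]
  if (!length(v)) stop("no finite SWIR values supplied")
  fallback <- function(msg) {
    warning("threshold fallback to window midpoint: ", msg)
    structure((t0 + t1) / 2, fallback = TRUE)
  }
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- hist(v, breaks = breaks, plot = FALSE)$counts
  centres <- breaks[-length(breaks)] + bin_width / 2
  inw <- centres >= t0 & centres <= t1
  if (!any(inw)) return(fallback("no histogram bin within [t0, t1]"))
  cw <- counts[inw]
  if (all(diff(cw) >= 0) || all(diff(cw) <= 0))
    return(fallback("histogram is monotone across the window (no valley)"))
  i <- which(cw == min(cw))[1]        # tie -> lower reflectance
  structure(centres[inw][i], fallback = FALSE)
}

#' Refine a lake mask with the adaptive threshold and quality rules
#'
#' Within the expanded area, keeps pixels whose 1640 nm surface
#' reflectance (the raw scene, not the water-leaving-corrected one: the
#' correction zeroes the NIR-SWIR over both surfaces and would destroy
#' the water/land contrast) is below the lake's threshold; removes
#' QA-flagged pixels (cloud, cloud shadow, snow/ice, mixed, other
#' noise); erodes one pixel inward (the 500 m land-adjacency buffer at
#' native resolution); then removes optically-shallow pixels whose
#' *water-leaving* blue reflectance exceeds `shallow_blue`. An empty
#' result marks the lake unobserved for this date (`refined_mask`
#' all-FALSE, `observed = FALSE`).
#'
#' @param scene The raw (uncorrected) [scene_stack] with a `swir1640`
#'   band.
#' @param region A `lake_region` with `buffer_mask` set; if `threshold`
#'   is `NA` it is computed by [find_threshold()].
#' @param t0,t1,bin_width Passed to [find_threshold()].
#' @param shallow_blue Water-leaving blue ceiling for optically-deep
#'   water (default 0.06; the original workflow used visual
#'   interpretation, which cannot be automated).
#' @param swir_band,blue_band Band names.
#' @param corrected Optional pre-computed [correct_water_leaving()]
#'   output for the same scene (supplies the blue band of the shallow
#'   test); derived internally when absent.
#' @return The region with `threshold`, `refined_mask` and `observed` set.
#' @export
refine_lake <- function(scene, region, t0 = 0.04, t1 = 0.12,
                        bin_width = 0.002, shallow_blue = 0.06,
                        swir_band = "swir1640", blue_band = "blue",
                        corrected = NULL) {
  stopifnot(inherits(scene, "scene_stack"), inherits(region, "lake_region"))
  if (is.null(region$buffer_mask))
    stop("region has no buffer_mask; call build_buffer() first")
  swir <- scene$bands[[swir_band]]
  if (is.null(swir)) stop("scene is missing band: ", swir_band)
  if (is.null(corrected)) corrected <- correct_water_leaving(scene)
  blue <- corrected$bands[[blue_band]]
  if (is.null(blue)) stop("scene is missing band: ", blue_band)

  if (is.na(region$threshold)) {
    thr <- find_threshold(swir[region$buffer_mask], t0 = t0, t1 = t1,
                          bin_width = bin_width)
    region$threshold <- as.numeric(thr)
    region$threshold_fallback <- isTRUE(attr(thr, "fallback"))
  }

  wet <- region$buffer_mask & !is.na(swir) & swir < region$threshold
  wet <- wet & !qa_blocked(scene$qa)
  wet <- erode3(wet)
  wet <- wet & !(!is.na(blue) & blue > shallow_blue)
  region$refined_mask <- wet
  region$observed <- any(wet)
  region
}

#' Normal water mask from multi-date occurrence
#'
#' A pixel belongs to a lake's normal water area when it is classified
#' as water in more than `occurrence_min` of the composites on which it
#' is observable (not blocked by cloud/shadow/ice/noise QA flags);
#' cloud-obscured composites carry no information and are excluded from
#' the denominator. Also derives the mask's area and its area-weighted
#' centroid in map coordinates.
#'
#' @param refined_masks List of per-date refined masks (logical matrices).
#' @param observable_masks List (parallel to `refined_masks`) of logical
#'   matrices, `TRUE` where the pixel was observable on that date; `NULL`
#'   means always observable.
#' @param occurrence_min Occurrence-frequency threshold (default 0.30,
#'   strict: kept iff frequency > threshold).
#' @param transform,pixel_size_m Georeference, see [scene_stack()].
#' @param lake_id,freezing Carried into the result.
#' @return A `normal_water_mask` object: `lake_id`, `mask`, `area_km2`,
#'   `centroid_x`, `centroid_y`, `freezing`, `occurrence` raster.
#' @export
normal_water_mask <- function(refined_masks, observable_masks = NULL,
                              occurrence_min = 0.30,
                              transform = c(0, 0, 1), pixel_size_m = 500,
                              lake_id = "lake_01", freezing = FALSE) {
  n <- length(refined_masks)
  if (!n) stop("at least one refined mask is required")
  dims <- dim(refined_masks[[1]])
  water_n <- matrix(0, dims[1], dims[2])
  obs_n <- matrix(0, dims[1], dims[2])
  for (i in seq_len(n)) {
    obs <- if (is.null(observable_masks)) matrix(TRUE, dims[1], dims[2])
           else observable_masks[[i]]
    water_n <- water_n + (refined_masks[[i]] & obs)
    obs_n <- obs_n + obs
  }
  occ <- ifelse(obs_n > 0, water_n / obs_n, 0)
  mask <- occ > occurrence_min
  area_km2 <- sum(mask) * (pixel_size_m / 1000)^2
  if (any(mask)) {
    rc <- which(mask, arr.ind = TRUE)
    xy <- pixel_to_xy(transform, rc[, 1], rc[, 2])
    cx <- mean(xy$x); cy <- mean(xy$y)
  } else {
    cx <- NA_real_; cy <- NA_real_
  }
  structure(list(lake_id = lake_id, mask = mask, area_km2 = area_km2,
                 centroid_x = cx, centroid_y = cy,
                 freezing = isTRUE(freezing), occurrence = occ),
            class = "normal_water_mask")
}
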