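# Synthetic scene generator. Emits 8-day-composite-like multiband scenes
# with known ground truth (water masks, per-lake FUI trajectories,
# planted outlier patches, cloud/ice QA flags) so that every downstream
# stage has an oracle. Observation model per band:
#   observed = intrinsic water-leaving reflectance
#            + flat additive offset (glint floor + sky/aerosol residual)
#            + Gaussian noise
# which is exactly the error structure the minimum-NIR/SWIR correction
# removes. Water-leaving reflectance in the NIR-SWIR is taken as zero, so
# the observed water SWIR equals the additive offset.

# run code with a local RNG state, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %%
               (.Machine$integer.max - 1)) + 1L
}

# Largest radius from the white point along direction `theta_deg` for
# which the inverted R,G,B stay non-negative. Linear in the radius:
# rgb(r) = S * Minv %*% (w + r d), w = (1/3,1/3,1/3).
.max_locus_radius <- function(theta_deg) {
  minv <- solve(.RGB2XYZ)
  th <- theta_deg * pi / 180
  d <- c(cos(th), sin(th), -cos(th) - sin(th))
  base <- as.vector(minv %*% rep(1 / 3, 3))
  slope <- as.vector(minv %*% d)
  lim <- ifelse(slope < 0, -base / slope, Inf)
  min(lim)
}

# Invert alpha_corrected = alpha + Delta(alpha) on the increasing branch.
# alpha + Delta(alpha) has a global minimum (~41.27 deg near alpha ~58.4),
# so corrected angles below it are unreachable; see delta_correction().
.delta_inverse <- function(target) {
  g <- function(a) a + delta_correction(a)$delta
  amin <- stats::optimize(g, c(0, 150))$minimum
  gmin <- g(amin)
  if (target < gmin)
    stop(sprintf(paste0(
      "corrected hue angle %.4f deg is unreachable: alpha + Delta(alpha) ",
      "has minimum %.4f deg; FUI classes 17-21 cannot be produced ",
      "through the satellite deviation-corrected path"), target, gmin))
  stats::uniroot(function(a) g(a) - target, c(amin, 359.999),
                 tol = 1e-10)$root
}

#' Invert a Forel-Ule class to band reflectances
#'
#' Produces red/green/blue/NIR/SWIR reflectances that encode a given FUI
#' class, for use in synthetic scenes. The chromaticity point is the
#' look-up-table point of the class itself (a unique, reproducible
#' inverse) at a fixed brightness `X + Y + Z`, converted to R, G, B by
#' inverting the tristimulus transform. The NIR and 1640 nm SWIR carry no
#' water-leaving signal: their values equal the additive offset (plus a
#' small NIR excess so that the per-pixel NIR-SWIR minimum is the SWIR).
#'
#' With `modis_bias = TRUE`, the hue angle is pre-distorted by the
#' inverse of the band-setting deviation polynomial so that the standard
#' satellite pipeline (which applies [delta_correction()]) classifies the
#' pixel back to `fui_class`. Because `alpha + Delta(alpha)` has a global
#' minimum near 41.3 degrees, classes 17-21 are unreachable through that
#' path and are rejected. With the default `modis_bias = FALSE`, the
#' emitted chromaticity equals the table point of the class and
#' round-trips through classification with the correction disabled, for
#' all 21 classes.
#'
#' @param fui_class Integer in `1..21` (`1..16` when `modis_bias = TRUE`).
#' @param residual_level Additive sky/aerosol/glint offset applied to all
#'   bands (reflectance units, >= 0).
#' @param noise_sd Gaussian noise standard deviation per band.
#' @param seed Integer seed for the noise draw (ignored if `noise_sd = 0`).
#' @param modis_bias Pre-distort for the deviation-corrected pipeline.
#' @param brightness Fixed tristimulus sum `X + Y + Z` (default 0.30,
#'   giving visible reflectances of a few percent, typical of water).
#' @param lut Look-up table, see [fui_lut()].
#' @return Named numeric vector `c(red, green, blue, nir, swir1640)`.
#' @export
fui_to_reflectance <- function(fui_class, residual_level = 0,
                               noise_sd = 0, seed = NULL,
                               modis_bias = FALSE, brightness = 0.30,
                               lut = fui_lut()) {
  if (length(fui_class) != 1L || !is.finite(fui_class) ||
      fui_class != round(fui_class) || fui_class < 1 || fui_class > 21)
    stop("fui_class must be a single integer in 1..21, got: ",
         deparse(substitute(fui_class)), " = ", format(fui_class))
  stopifnot(residual_level >= 0, noise_sd >= 0)
  k <- as.integer(fui_class)

  if (modis_bias) {
    target <- lut$alpha[k]
    a0 <- .delta_inverse(target)   # errors for unreachable classes
    rk <- sqrt((lut$x[k] - 1 / 3)^2 + (lut$y[k] - 1 / 3)^2)
    r <- min(rk, 0.9 * .max_locus_radius(a0))
    x <- 1 / 3 + r * cos(a0 * pi / 180)
    y <- 1 / 3 + r * sin(a0 * pi / 180)
  } else {
    x <- lut$x[k]
    y <- lut$y[k]
  }

  xyz <- c(x, y, 1 - x - y) * brightness
  rgb <- as.vector(solve(.RGB2XYZ) %*% xyz)
  rgb[rgb < 0 & rgb > -1e-12] <- 0   # numerical dust only
  if (any(rgb < 0))
    stop("internal error: negative reflectance for class ", k)

  out <- c(red = rgb[1] + residual_level,
           green = rgb[2] + residual_level,
           blue = rgb[3] + residual_level,
           nir = residual_level + 0.005,
           swir1640 = residual_level)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(5, 0, noise_sd)
             else .with_seed(seed, stats::rnorm(5, 0, noise_sd))
    out <- pmax(out + noise, 0)
  }
  out
}

#' Specify a synthetic lake
#'
#' @param center Pixel-coordinate centre `c(row, col)` of the lake.
#' @param radii Semi-axes in pixels, `c(row_radius, col_radius)`; a
#'   scalar gives a disc. Ignored when `polygon` is supplied.
#' @param polygon Optional two-column matrix of (row, col) vertices of a
#'   simple polygon in pixel coordinates (even-odd fill rule).
#' @param fui Either a single FUI class used for all dates, or a function
#'   `function(date) -> class` giving the true trajectory.
#' @param freezing Logical: does the lake carry ice November-April?
#' @param shallow_margin_pixels Number of optically-shallow rim rings
#'   (each ring is one pixel wide) whose blue band is inflated so the
#'   shallow-water exclusion can be exercised.
#' @return An object of class `lake_spec`.
#' @export
lake_spec <- function(center, radii = NULL, polygon = NULL, fui = 5,
                      freezing = FALSE, shallow_margin_pixels = 0) {
  if (is.null(polygon)) {
    stopifnot(length(center) == 2L, !is.null(radii))
    if (length(radii) == 1L) radii <- c(radii, radii)
  }
  structure(list(center = center, radii = radii, polygon = polygon,
                 fui = fui, freezing = isTRUE(freezing),
                 shallow_margin_pixels = as.integer(shallow_margin_pixels)),
            class = "lake_spec")
}

#' Specify a synthetic scene
#'
#' Fixes the stated world a synthetic scene is drawn from: grid shape,
#' lake geometries and true-colour trajectories, land/water SWIR levels,
#' the additive sky/aerosol residual, cloud cover and noise.
#'
#' @param grid_shape `c(rows, cols)`, both positive.
#' @param lakes List of [lake_spec()] objects. Lakes must not overlap,
#'   touch each other, or touch the grid edge, and must each cover at
#'   least 100 pixels (25 km^2 at 500 m).
#' @param pixel_size_m Ground pixel size in metres (default 500).
#' @param land_swir_level 1640 nm reflectance of land (default 0.20).
#' @param land_swir_sd Standard deviation of the land 1640 nm
#'   heterogeneity (default 0.03, truncated so land never drops below
#'   0.05 above the residual): real land covers spread a tail into the
#'   threshold window, which is what makes the histogram bimodal rather
#'   than two spikes.
#' @param water_swir_level Observed 1640 nm floor over water, i.e. the
#'   surface glint/skylight part of the additive offset (default 0.02;
#'   water-leaving SWIR itself is zero).
#' @param residual_level Additional scene-wide additive sky/aerosol
#'   residual (default 0.01; the product-level correction leaves a
#'   residual of this order and it must stay configurable).
#' @param noise_sd Per-band Gaussian noise standard deviation
#'   (default 0.001).
#' @param cloud_fraction Fraction of the grid covered by cloud blobs,
#'   in `[0, 1]`.
#' @param modis_bias Encode spectra for the deviation-corrected satellite
#'   path (default `TRUE`; restricts classes to 1..16, see
#'   [fui_to_reflectance()]).
#' @param transform,crs Georeference, see [scene_stack()].
#' @param seed Integer master seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(grid_shape, lakes,
                       pixel_size_m = 500,
                       land_swir_level = 0.20,
                       land_swir_sd = 0.03,
                       water_swir_level = 0.02,
                       residual_level = 0.01,
                       noise_sd = 0.001,
                       cloud_fraction = 0,
                       modis_bias = TRUE,
                       transform = NULL, crs = "local-metric",
                       seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1),
            cloud_fraction >= 0, cloud_fraction <= 1,
            water_swir_level < land_swir_level,
            residual_level >= 0, noise_sd >= 0)
  if (!length(lakes) || !all(vapply(lakes, inherits, TRUE, "lake_spec")))
    stop("lakes must be a non-empty list of lake_spec objects")
  if (is.null(transform))
    transform <- c(0, grid_shape[1] * pixel_size_m, pixel_size_m)
  structure(list(grid_shape = as.integer(grid_shape), lakes = lakes,
                 pixel_size_m = pixel_size_m,
                 land_swir_level = land_swir_level,
                 land_swir_sd = land_swir_sd,
                 water_swir_level = water_swir_level,
                 residual_level = residual_level, noise_sd = noise_sd,
                 cloud_fraction = cloud_fraction, modis_bias = modis_bias,
                 transform = transform, crs = crs,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# rasterise one lake_spec to a logical matrix
.lake_mask <- function(lake, grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (!is.null(lake$polygon)) {
    p <- lake$polygon
    np <- nrow(p)
    inside <- matrix(FALSE, nr, nc)
    j <- np
    for (i in seq_len(np)) {
      yi <- p[i, 1]; xi <- p[i, 2]
      yj <- p[j, 1]; xj <- p[j, 2]
      crosses <- ((yi > rr) != (yj > rr)) &
        (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    inside
  } else {
    ((rr - lake$center[1]) / lake$radii[1])^2 +
      ((cc - lake$center[2]) / lake$radii[2])^2 <= 1
  }
}

.resolve_fui <- function(lake, date) {
  k <- if (is.function(lake$fui)) lake$fui(date) else lake$fui
  as.integer(round(k))
}

# cloud blobs: random discs until coverage target is met
.cloud_mask <- function(grid_shape, fraction) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  m <- matrix(FALSE, nr, nc)
  if (fraction <= 0) return(m)
  target <- fraction * nr * nc
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  guard <- 0L
  while (sum(m) < target && guard < 10000L) {
    r0 <- stats::runif(1, 1, nr)
    c0 <- stats::runif(1, 1, nc)
    rad <- stats::runif(1, 2, 5)
    m <- m | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
    guard <- guard + 1L
  }
  m
}

#' Generate one synthetic scene with ground truth
#'
#' Renders the lakes of a [scene_spec()] onto a land background for one
#' composite date: water pixels carry spectra encoding the lake's true
#' FUI class (via [fui_to_reflectance()]), land pixels have high 1640 nm
#' reflectance, all bands share the flat additive offset, and the QA band
#' marks inland water, cloud blobs and (optionally) ice. Deterministic
#' for a fixed spec and seed.
#'
#' @param spec A [scene_spec()].
#' @param date Composite date (`Date`).
#' @param seed Scene seed; defaults to the spec's master seed.
#' @param ice_lakes Integer indices of lakes to flag as ice-covered (QA
#'   snow/ice over the whole lake), used for freezing lakes in winter.
#' @param outlier_patches Optional list (parallel to lakes) of `NULL` or
#'   a list `list(mask = <logical matrix>, fui = <class>)` describing a
#'   planted deviant patch, as produced by [generate_series()].
#' @return A list with components `scene` (a [scene_stack]) and `truth`
#'   (list: `water_mask`, `fui` truth raster, `qa`, `lake_masks`,
#'   `lake_fui`, `outliers`).
#' @export
generate_scene <- function(spec, date = as.Date("2001-07-04"),
                           seed = NULL, ice_lakes = integer(0),
                           outlier_patches = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(seed)) seed <- spec$seed
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]

  lake_masks <- lapply(spec$lakes, .lake_mask, grid_shape = spec$grid_shape)
  # validity: area, no edge contact, no overlap/adjacency between lakes
  occupied <- matrix(FALSE, nr, nc)
  for (i in seq_along(lake_masks)) {
    m <- lake_masks[[i]]
    if (sum(m) < 100)
      stop("lake ", i, " covers ", sum(m),
           " pixels; lakes must cover >= 100 pixels (> 25 km^2 at 500 m)")
    if (any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc]))
      stop("lake ", i, " touches the grid edge")
    if (any(dilate3(m) & occupied))
      stop("lakes overlap or touch each other (lake ", i, ")")
    occupied <- occupied | m
  }
  water_mask <- occupied

  offset <- spec$water_swir_level + spec$residual_level
  truth_fui <- matrix(NA_integer_, nr, nc)
  lake_fui <- integer(length(spec$lakes))

  # land background (broad-band typical vegetated/soil values)
  bands <- list(
    red = matrix(0.10, nr, nc), green = matrix(0.11, nr, nc),
    blue = matrix(0.08, nr, nc), nir = matrix(0.25, nr, nc),
    swir1640 = matrix(spec$land_swir_level, nr, nc)
  )
  for (nm in names(bands)) bands[[nm]] <- bands[[nm]] + spec$residual_level

  for (i in seq_along(spec$lakes)) {
    lake <- spec$lakes[[i]]
    m <- lake_masks[[i]]
    k <- .resolve_fui(lake, date)
    lake_fui[i] <- k
    truth_fui[m] <- k
    spec_k <- fui_to_reflectance(k, residual_level = 0, noise_sd = 0,
                                 modis_bias = spec$modis_bias)
    bands$red[m] <- spec_k[["red"]] + offset
    bands$green[m] <- spec_k[["green"]] + offset
    bands$blue[m] <- spec_k[["blue"]] + offset
    bands$nir[m] <- offset + 0.005
    bands$swir1640[m] <- offset

    patch <- if (!is.null(outlier_patches)) outlier_patches[[i]] else NULL
    if (!is.null(patch)) {
      pm <- patch$mask & m
      dev_k <- fui_to_reflectance(patch$fui, residual_level = 0,
                                  noise_sd = 0,
                                  modis_bias = spec$modis_bias)
      bands$red[pm] <- dev_k[["red"]] + offset
      bands$green[pm] <- dev_k[["green"]] + offset
      bands$blue[pm] <- dev_k[["blue"]] + offset
    }

    if (lake$shallow_margin_pixels > 0) {
      core <- m
      for (j in seq_len(lake$shallow_margin_pixels)) core <- erode3(core)
      rim <- m & !core
      bands$blue[rim] <- pmax(bands$blue[rim], 0.08 + offset)
      truth_shallow <- attr(truth_fui, "shallow")
      sh <- if (is.null(truth_shallow)) matrix(FALSE, nr, nc) else truth_shallow
      sh[rim] <- TRUE
      attr(truth_fui, "shallow") <- sh
    }
  }

  qa <- matrix(0L, nr, nc)
  qa[water_mask] <- bitwShiftL(1L, .QA_BITS[["inland_water"]])

  scene <- .with_seed(seed, {
    # RNG stream order per scene: land heterogeneity, clouds, band noise
    if (spec$land_swir_sd > 0) {
      land_px <- !water_mask
      floor_land <- 0.05 + spec$residual_level
      bands$swir1640[land_px] <- pmax(
        bands$swir1640[land_px] +
          stats::rnorm(sum(land_px), 0, spec$land_swir_sd), floor_land)
    }
    cloud <- .cloud_mask(spec$grid_shape, spec$cloud_fraction)
    qa[cloud] <- bitwOr(qa[cloud], bitwShiftL(1L, .QA_BITS[["cloud"]]))
    for (i in ice_lakes) {
      im <- lake_masks[[i]]
      qa[im] <- bitwOr(qa[im], bitwShiftL(1L, .QA_BITS[["snow_ice"]]))
    }
    if (spec$noise_sd > 0)
      for (nm in names(bands))
        bands[[nm]] <- pmax(bands[[nm]] +
          matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0)
    # clouds are bright in all bands
    for (nm in names(bands)) bands[[nm]][cloud] <- 0.35
    scene_stack(date, bands, qa, transform = spec$transform,
                crs = spec$crs, pixel_size_m = spec$pixel_size_m)
  })

  list(scene = scene,
       truth = list(water_mask = water_mask, fui = truth_fui,
                    qa = scene$qa, lake_masks = lake_masks,
                    lake_fui = lake_fui,
                    shallow = attr(truth_fui, "shallow")))
}

# contiguous random patch of ~frac of the lake's pixels
.grow_patch <- function(mask, frac) {
  target <- max(1L, round(frac * sum(mask)))
  idx <- which(mask)
  seed_px <- idx[sample.int(length(idx), 1L)]
  patch <- matrix(FALSE, nrow(mask), ncol(mask))
  patch[seed_px] <- TRUE
  while (sum(patch) < target) {
    grown <- dilate3(patch) & mask
    if (all(grown == patch)) break
    patch <- grown
  }
  patch
}

#' Generate a multi-date synthetic scene series with ground truth
#'
#' Draws one scene per composite date. Each lake's true FUI follows its
#' trajectory function (or a seasonal sinusoid built from `fui` base
#' class and `seasonal_amplitude`, peaking in boreal summer, rounded to
#' classes). With probability `outlier_rate` per lake and date, a
#' contiguous patch covering 10-30% of the lake is planted with a
#' deviant class (emulating undetected thin cloud or glint) and recorded
#' in the truth table. Freezing lakes carry QA snow/ice flags on all
#' November-April scenes.
#'
#' @param spec A [scene_spec()].
#' @param dates Sorted, unique `Date` vector of composite dates.
#' @param seasonal_amplitude Peak deviation from the base class, in FUI
#'   classes (default 2; applied only to lakes whose `fui` is a scalar).
#' @param outlier_rate Per-lake, per-date probability of a planted
#'   outlier patch, in `[0, 1]`.
#' @param trend_per_year Linear drift of the true class per year
#'   (default 0; applied to scalar-`fui` lakes).
#' @return A list of per-date results as from [generate_scene()], with
#'   attributes `truth_table` (data frame: date, lake, true_fui,
#'   outlier, outlier_fui, outlier_pixels) and `dates`.
#' @export
generate_series <- function(spec, dates, seasonal_amplitude = 2,
                            outlier_rate = 0, trend_per_year = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!length(dates)) stop("dates must be a non-empty Date vector")
  dates <- as.Date(dates)
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be sorted and unique")
  stopifnot(outlier_rate >= 0, outlier_rate <= 1)

  kmax <- if (spec$modis_bias) 16L else 21L
  t0 <- dates[1]
  traj <- function(lake, date) {
    if (is.function(lake$fui)) return(.resolve_fui(lake, date))
    doy <- as.integer(format(date, "%j"))
    yrs <- as.numeric(date - t0) / 365.25
    k <- lake$fui + seasonal_amplitude * sin(2 * pi * (doy - 112) / 365) +
      trend_per_year * yrs
    max(1L, min(kmax, as.integer(round(k))))
  }

  n_lakes <- length(spec$lakes)
  out <- vector("list", length(dates))
  tt <- vector("list", length(dates))
  for (di in seq_along(dates)) {
    date <- dates[di]
    seed_i <- .derive_seed(spec$seed, di)
    month <- as.integer(format(date, "%m"))
    winter <- month >= 11L | month <= 4L
    ice <- if (winter)
      which(vapply(spec$lakes, function(l) l$freezing, TRUE)) else integer(0)

    res <- .with_seed(.derive_seed(seed_i, 500000L), {
      patches <- vector("list", n_lakes)
      rec <- data.frame(date = rep(date, n_lakes), lake = seq_len(n_lakes),
                        true_fui = NA_integer_, outlier = FALSE,
                        outlier_fui = NA_integer_,
                        outlier_pixels = 0L)
      for (i in seq_len(n_lakes)) {
        lk <- spec$lakes[[i]]
        k <- traj(lk, date)
        rec$true_fui[i] <- k
        if (outlier_rate > 0 && stats::runif(1) < outlier_rate) {
          mask_i <- .lake_mask(lk, spec$grid_shape)
          dev <- if (k <= kmax / 2) min(kmax, k + 6L) else max(1L, k - 6L)
          pm <- .grow_patch(mask_i, stats::runif(1, 0.10, 0.30))
          patches[[i]] <- list(mask = pm, fui = dev)
          rec$outlier[i] <- TRUE
          rec$outlier_fui[i] <- dev
          rec$outlier_pixels[i] <- sum(pm)
        }
      }
      list(patches = patches, rec = rec)
    })

    # freeze the per-date trajectory into the spec via fixed classes
    spec_i <- spec
    for (i in seq_len(n_lakes)) spec_i$lakes[[i]]$fui <- res$rec$true_fui[i]
    out[[di]] <- generate_scene(spec_i, date = date, seed = seed_i,
                                ice_lakes = ice,
                                outlier_patches = res$patches)
    tt[[di]] <- res$rec
  }
  attr(out, "truth_table") <- do.call(rbind, tt)
  attr(out, "dates") <- dates
  out
}
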