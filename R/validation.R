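# Matchup construction and agreement statistics between satellite-derived
# and field-derived FUI: mean relative difference, root-mean-square
# error, rectangular band resampling of field spectra, and Pearson
# correlation for cross-dataset comparison.

#' Mean relative difference (percent)
#'
#' `MRD = 100/n * sum(|est_i - mea_i| / mea_i)`. Not symmetric in its
#' arguments: the measured series is the reference in the denominator.
#'
#' @param estimated,measured Equal-length numeric vectors; `measured`
#'   must be strictly positive.
#' @return MRD in percent.
#' @export
#' @examples
#' mrd(11, 10) # 10
mrd <- function(estimated, measured) {
  if (length(estimated) != length(measured) || !length(measured))
    stop("estimated and measured must have equal, positive length")
  if (any(!is.finite(measured)) || any(measured <= 0))
    stop("measured values must be positive (relative difference undefined)")
  mean(abs(estimated - measured) / measured) * 100
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((est - mea)^2))` (n denominator); symmetric in its
#' arguments, in the units of the input.
#'
#' @inheritParams mrd
#' @return RMSE.
#' @export
rmse <- function(estimated, measured) {
  if (length(estimated) != length(measured) || !length(measured))
    stop("estimated and measured must have equal, positive length")
  sqrt(mean((estimated - measured)^2))
}

#' Resample a reflectance spectrum to nominal sensor bands
#'
#' Unweighted mean of the spectral values falling inside each nominal
#' band window (rectangular spectral response; true sensor response
#' functions are not modelled). The spectrum must cover every window and
#' contain no NA inside one.
#'
#' @param wavelengths Numeric vector (nm), increasing.
#' @param reflectance Numeric vector, same length.
#' @param band_windows Named list of `c(min_nm, max_nm)` windows;
#'   defaults to the 500 m sensor's visible bands
#'   (red 620-670, green 545-565, blue 459-479 nm).
#' @return Named numeric vector of band reflectances.
#' @export
#' @examples
#' wl <- 400:700
#' resample_spectrum_to_bands(wl, wl / 10000)[["green"]] # 0.0555
resample_spectrum_to_bands <- function(wavelengths, reflectance,
                                       band_windows = list(
                                         red = c(620, 670),
                                         green = c(545, 565),
                                         blue = c(459, 479))) {
  stopifnot(length(wavelengths) == length(reflectance))
  out <- numeric(length(band_windows))
  names(out) <- names(band_windows)
  for (nm in names(band_windows)) {
    w <- band_windows[[nm]]
    if (min(wavelengths) > w[1] || max(wavelengths) < w[2])
      stop("spectrum does not cover band '", nm, "' (",
           w[1], "-", w[2], " nm)")
    inw <- wavelengths >= w[1] & wavelengths <= w[2]
    if (!any(inw))
      stop("no spectral samples inside band '", nm, "'")
    v <- reflectance[inw]
    if (any(!is.finite(v)))
      stop("non-finite reflectance inside band '", nm, "'")
    out[nm] <- mean(v)
  }
  out
}

#' FUI from a field reflectance spectrum
#'
#' Band-resamples a water-leaving reflectance spectrum to the visible
#' bands and classifies the resulting colour. The band-setting deviation
#' correction is skipped by default: it models the offset of the
#' satellite's broad bands, not hyperspectrally resampled true colour.
#'
#' @inheritParams resample_spectrum_to_bands
#' @param apply_delta Apply [delta_correction()] (default `FALSE`).
#' @param lut Look-up table.
#' @return FUI class (integer).
#' @export
fui_from_spectrum <- function(wavelengths, reflectance,
                              band_windows = list(red = c(620, 670),
                                                  green = c(545, 565),
                                                  blue = c(459, 479)),
                              apply_delta = FALSE, lut = fui_lut()) {
  b <- resample_spectrum_to_bands(wavelengths, reflectance, band_windows)
  xyz <- rgb_to_xyz(b[["red"]], b[["green"]], b[["blue"]])
  xy <- xyz_to_xy(xyz$X, xyz$Y, xyz$Z)
  alpha <- hue_angle(xy$x, xy$y)
  if (apply_delta) alpha <- delta_correction(alpha)$alpha_corrected
  classify_fui(alpha, lut)
}

#' Build satellite / field matchups
#'
#' For each sampling site, selects the nearest raster pixel (planar
#' distance in the raster grid) and the nearest date within a +/- 1 day
#' window (ties go to the nearest in time, then the earlier date).
#' Sites with no date in the window, an off-grid location, or no valid
#' satellite FUI at the pixel are dropped with a logged reason.
#'
#' @param sites Data frame with columns `x`, `y` (map coordinates),
#'   `date` (`Date`), and `fui_insitu` (precomputed, e.g. via
#'   [fui_from_spectrum()]).
#' @param fui_rasters Named list of FUI matrices; names are dates
#'   (`"%Y-%m-%d"`).
#' @param transform Affine transform shared by the rasters.
#' @param max_gap_days Matchup time window (default 1, inclusive).
#' @return A list: `matchups` (data frame with `site`, `date_insitu`,
#'   `date_satellite`, `time_gap_days`, `row`, `col`, `fui_insitu`,
#'   `fui_satellite`) and `dropped` (data frame with `site`, `reason`).
#' @export
build_matchups <- function(sites, fui_rasters, transform,
                           max_gap_days = 1) {
  stopifnot(all(c("x", "y", "date", "fui_insitu") %in% names(sites)))
  raster_dates <- as.Date(names(fui_rasters))
  if (any(is.na(raster_dates)))
    stop("fui_rasters must be named by ISO date")
  dims <- dim(fui_rasters[[1]])
  keep <- list(); drop <- list()
  for (i in seq_len(nrow(sites))) {
    gaps <- as.numeric(raster_dates - as.Date(sites$date[i]))
    cand <- which(abs(gaps) <= max_gap_days)
    if (!length(cand)) {
      drop[[length(drop) + 1L]] <-
        data.frame(site = i, reason = "no raster within time window")
      next
    }
    cand <- cand[order(abs(gaps[cand]), raster_dates[cand])]
    px <- xy_to_pixel(transform, sites$x[i], sites$y[i])
    if (px$row < 1 || px$row > dims[1] || px$col < 1 || px$col > dims[2]) {
      drop[[length(drop) + 1L]] <-
        data.frame(site = i, reason = "site outside raster grid")
      next
    }
    fui_sat <- NA_integer_; j_used <- NA_integer_
    for (j in cand) {
      v <- fui_rasters[[j]][px$row, px$col]
      if (is.finite(v)) { fui_sat <- v; j_used <- j; break }
    }
    if (!is.finite(fui_sat)) {
      drop[[length(drop) + 1L]] <-
        data.frame(site = i, reason = "no valid satellite FUI at pixel")
      next
    }
    keep[[length(keep) + 1L]] <- data.frame(
      site = i, date_insitu = as.Date(sites$date[i]),
      date_satellite = raster_dates[j_used],
      time_gap_days = gaps[j_used], row = px$row, col = px$col,
      fui_insitu = sites$fui_insitu[i], fui_satellite = fui_sat)
  }
  list(matchups = if (length(keep)) do.call(rbind, keep) else
         data.frame(site = integer(0)),
       dropped = if (length(drop)) do.call(rbind, drop) else
         data.frame(site = integer(0), reason = character(0)))
}

#' Pearson product-moment correlation
#'
#' @param series_a,series_b Paired numeric vectors (NAs dropped
#'   pairwise); at least 3 complete pairs and nonzero variance in both.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(series_a, series_b) {
  ok <- is.finite(series_a) & is.finite(series_b)
  a <- series_a[ok]; b <- series_b[ok]
  if (length(a) < 3) stop("need at least 3 paired observations")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("correlation undefined for zero-variance series")
  stats::cor(a, b)
}
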