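# Monthly and yearly per-lake FUI: temporal (mu +/- 3 sigma) and spatial
# (mu +/- 1.5 sigma) single-pass outlier filters, the 30% coverage rule,
# freezing-lake May-October restriction, per-year validity minima,
# interior linear gap filling, yearly means and OLS trend tests.

#' Temporal outlier filter (mu +/- k sigma, single pass)
#'
#' Removes values outside `[mu - k sigma, mu + k sigma]` where `mu` and
#' `sigma` (sample standard deviation, n-1 denominator) are computed once
#' over the input; no re-iteration after removal. With fewer than 3
#' values sigma is unreliable and nothing is removed. A warning is
#' emitted if more than half the sample would be removed.
#'
#' @param values Numeric vector (one pixel's FUI across the composites of
#'   one month, in the standard use).
#' @param k Window half-width in standard deviations (default 3).
#' @return The retained values.
#' @export
#' @examples
#' temporal_filter(c(rep(10, 29), 100)) # drops the 100
temporal_filter <- function(values, k = 3) {
  v <- values[is.finite(values)]
  if (length(v) < 3L) return(v)
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v)
  keep <- abs(v - mu) <= k * s
  if (sum(!keep) > length(v) / 2) {
    warning("temporal filter would remove more than half the sample; ",
            "removal skipped")
    return(v)
  }
  v[keep]
}

#' Monthly FUI composite of one lake
#'
#' Per-pixel temporal filtering and averaging of the 8-day FUI rasters
#' falling in one month: at each normal-mask pixel, values outside the
#' `mu +/- k sigma` window across the month's composites are removed
#' (single pass, no removal when fewer than 3 observations) and the
#' survivors averaged. Pixels with no valid observation are `NA`.
#'
#' @param fui_rasters List of integer/numeric matrices (`NA` = not
#'   observed), all aligned with `mask`.
#' @param mask Logical matrix (the lake's normal water mask).
#' @param k Temporal window half-width (default 3).
#' @return Numeric matrix: monthly mean FUI inside `mask`, `NA` elsewhere.
#' @export
monthly_composite <- function(fui_rasters, mask, k = 3) {
  if (!length(fui_rasters)) stop("no rasters supplied for this month")
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  m <- vapply(fui_rasters, function(r) as.numeric(r[idx]),
              numeric(length(idx)))
  m <- matrix(m, nrow = length(idx))
  n_obs <- rowSums(is.finite(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums(m * m, na.rm = TRUE)
  s2 <- (ss - n_obs * mu^2) / pmax(n_obs - 1, 1)
  s <- sqrt(pmax(s2, 0))
  # keep: inside window, or too few values for sigma, or sigma zero
  keep <- is.finite(m) &
    (n_obs[row(m)] < 3 | s[row(m)] == 0 |
       abs(m - mu[row(m)]) <= k * s[row(m)])
  removed <- is.finite(m) & !keep
  over <- rowSums(removed) > n_obs / 2
  if (any(over)) {
    warning("temporal filter would remove more than half the ",
            "observations at ", sum(over), " pixel(s); removal skipped")
    keep[over, ] <- is.finite(m)[over, , drop = FALSE]
  }
  msum <- rowSums(ifelse(keep, m, 0), na.rm = TRUE)
  nkeep <- rowSums(keep)
  out <- matrix(NA_real_, dims[1], dims[2])
  out[idx] <- ifelse(nkeep > 0, msum / nkeep, NA_real_)
  out
}

#' Spatial lake mean with outlier trimming and coverage rule
#'
#' Computes the lake-mean FUI of a monthly raster within the normal
#' water mask. If the observed fraction of mask pixels (`coverage`) is
#' not above `min_coverage` the month is invalid (`NA` mean). Otherwise
#' pixel values outside the single-pass `mu +/- k sigma` window are
#' trimmed and the survivors averaged.
#'
#' @param monthly_raster Numeric matrix from [monthly_composite()].
#' @param mask Logical matrix (normal water mask).
#' @param k Spatial window half-width (default 1.5).
#' @param min_coverage Minimum observed fraction (default 0.30, strict).
#' @return A one-row data frame: `fui`, `n_pixels_used`, `coverage`,
#'   `valid`.
#' @export
#' @examples
#' m <- matrix(c(rep(10, 9), 20), 2, 5)
#' spatial_mean(m, matrix(TRUE, 2, 5))$fui # 10
spatial_mean <- function(monthly_raster, mask, k = 1.5,
                         min_coverage = 0.30) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  v <- monthly_raster[idx]
  obs <- is.finite(v)
  coverage <- mean(obs)
  if (coverage <= min_coverage)
    return(data.frame(fui = NA_real_, n_pixels_used = 0L,
                      coverage = coverage, valid = FALSE))
  v <- v[obs]
  mu <- mean(v)
  s <- stats::sd(v)
  keep <- if (!is.finite(s) || s == 0) rep(TRUE, length(v))
          else abs(v - mu) <= k * s
  if (sum(!keep) > length(v) / 2) {
    warning("spatial filter would remove more than half the pixels; ",
            "removal skipped")
    keep <- rep(TRUE, length(v))
  }
  data.frame(fui = mean(v[keep]), n_pixels_used = sum(keep),
             coverage = coverage, valid = TRUE)
}

#' Apply per-year validity rules to a monthly series
#'
#' Freezing lakes are restricted to boreal May-October before counting
#' (ice changes the observed colour); a calendar year is valid when it
#' has at least `min_months_freezing` (freezing) or
#' `min_months_nonfreezing` (non-freezing) valid months. By default a
#' lake failing the rule in any year is excluded from the dataset
#' entirely; with `drop_lake_on_any_bad_year = FALSE` only the failing
#' years are dropped.
#'
#' @param series Data frame with columns `year`, `month`, `fui`, `valid`
#'   (one row per lake-month), sorted by month.
#' @param freezing Logical.
#' @param min_months_nonfreezing,min_months_freezing Validity minima
#'   (defaults 6 and 3).
#' @param drop_lake_on_any_bad_year See above (default `TRUE`).
#' @return A list: `series` (kept rows), `lake_included` (logical),
#'   `bad_years` (integer vector).
#' @export
apply_validity_rules <- function(series, freezing = FALSE,
                                 min_months_nonfreezing = 6,
                                 min_months_freezing = 3,
                                 drop_lake_on_any_bad_year = TRUE) {
  stopifnot(all(c("year", "month", "fui", "valid") %in% names(series)))
  if (freezing) series <- series[series$month >= 5 & series$month <= 10, ]
  min_months <- if (freezing) min_months_freezing else min_months_nonfreezing
  years <- sort(unique(series$year))
  n_valid <- vapply(years, function(y)
    sum(series$valid[series$year == y], na.rm = TRUE), integer(1))
  bad <- years[n_valid < min_months]
  if (length(bad) && drop_lake_on_any_bad_year)
    return(list(series = series[0, ], lake_included = FALSE,
                bad_years = bad))
  keep <- !(series$year %in% bad)
  list(series = series[keep, ], lake_included = TRUE, bad_years = bad)
}

#' Fill interior gaps in a monthly series by linear interpolation
#'
#' Missing months strictly between two valid months are filled linearly
#' on the month index; leading and trailing gaps are left missing. For
#' freezing lakes interpolation is confined to each year's May-October
#' window (no interpolation across winters). Idempotent; never alters
#' non-missing values.
#'
#' @param series Data frame with columns `year`, `month`, `fui` (NA =
#'   missing), sorted in time.
#' @param freezing Logical.
#' @return The series with columns `fui_filled` and `filled` added.
#' @export
#' @examples
#' s <- data.frame(year = 2001, month = 1:3, fui = c(4, NA, 6))
#' fill_gaps(s)$fui_filled # 4 5 6
fill_gaps <- function(series, freezing = FALSE) {
  stopifnot(all(c("year", "month", "fui") %in% names(series)))
  series$fui_filled <- series$fui
  series$filled <- FALSE
  fill_block <- function(rows) {
    v <- series$fui[rows]
    if (sum(is.finite(v)) >= 2) {
      t <- seq_along(v)
      f <- stats::approx(t[is.finite(v)], v[is.finite(v)], xout = t,
                         method = "linear", rule = 1)$y
      miss <- !is.finite(v) & is.finite(f)
      series$fui_filled[rows][miss] <<- f[miss]
      series$filled[rows][miss] <<- TRUE
    }
  }
  if (freezing) {
    for (y in unique(series$year))
      fill_block(which(series$year == y &
                         series$month >= 5 & series$month <= 10))
  } else {
    # global month index keeps spacing even across year boundaries
    ord <- order(series$year, series$month)
    fill_block(ord)
  }
  series
}

#' Yearly mean FUI
#'
#' Arithmetic mean of a year's monthly values (raw and filled alike).
#'
#' @param series Data frame with `year` and `fui_filled` (or `fui`).
#' @param year Calendar year.
#' @return Numeric scalar, `NA` if the year has no valid month.
#' @export
yearly_mean <- function(series, year) {
  col <- if ("fui_filled" %in% names(series)) "fui_filled" else "fui"
  v <- series[[col]][series$year == year]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Linear trend of yearly FUI
#'
#' Ordinary-least-squares slope of yearly FUI on calendar year with a
#' two-sided t-test on the slope, or the Mann-Kendall test with Sen's
#' slope as a nonparametric alternative.
#'
#' @param years Integer vector of calendar years (>= 3 distinct).
#' @param values Yearly FUI values (same length; NAs dropped pairwise).
#' @param method `"ols"` (default) or `"mann-kendall"`.
#' @return A list: `slope` (FUI per year), `p_value` (two-sided).
#' @export
#' @examples
#' annual_trend(2001:2005, c(5, 6, 7, 8, 9))$slope # 1
annual_trend <- function(years, values, method = c("ols", "mann-kendall")) {
  method <- match.arg(method)
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  if (length(unique(years)) < 3)
    stop("trend requires at least 3 years of data")
  if (method == "ols") {
    if (stats::var(values) == 0)
      return(list(slope = 0, p_value = 1))
    fit <- stats::lm(values ~ years)
    # exact fits have zero residual variance; summary.lm would warn
    sm <- suppressWarnings(summary(fit)$coefficients)
    p <- unname(sm["years", "Pr(>|t|)"])
    if (unname(sm["years", "Std. Error"]) == 0) p <- 0
    list(slope = unname(sm["years", "Estimate"]), p_value = p)
  } else {
    n <- length(values)
    pairs <- utils::combn(n, 2)
    d <- values[pairs[2, ]] - values[pairs[1, ]]
    dt <- years[pairs[2, ]] - years[pairs[1, ]]
    s_stat <- sum(sign(d))
    var_s <- n * (n - 1) * (2 * n + 5) / 18
    z <- if (s_stat > 0) (s_stat - 1) / sqrt(var_s)
         else if (s_stat < 0) (s_stat + 1) / sqrt(var_s) else 0
    list(slope = stats::median(d / dt),
         p_value = 2 * stats::pnorm(-abs(z)))
  }
}
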