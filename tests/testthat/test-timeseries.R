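test_that("temporal filter trims only clear outliers, single pass", {
  # constant series is untouched (sigma = 0)
  expect_identical(temporal_filter(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  # worked example: 29 tens and one 100 -> the 100 is removed
  v <- c(rep(10, 29), 100)
  expect_identical(temporal_filter(v), rep(10, 29))
  # direct mu/sigma arithmetic oracle for the same input
  mu <- mean(v); s <- sd(v)
  expect_identical(temporal_filter(v), v[abs(v - mu) <= 3 * s])
  # fewer than 3 values: sigma unreliable, nothing removed
  expect_identical(temporal_filter(c(5, 50)), c(5, 50))
  # never removes more than half the sample in one pass
  w <- c(1, 1, 100, 100, 100)
  expect_warning(out <- temporal_filter(w, k = 0.1), "half")
  expect_identical(out, w)
})

test_that("monthly composite averages temporally filtered pixels", {
  mask <- matrix(TRUE, 2, 2)
  r <- matrix(c(5, 6, 7, 8), 2, 2)
  # identical rasters -> composite equals any input
  expect_equal(monthly_composite(rep(list(r), 4), mask), r)
  # month with zero valid observations -> fully missing
  rna <- matrix(NA_real_, 2, 2)
  expect_true(all(is.na(monthly_composite(list(rna, rna), mask))))
  # partial cloud: pixelwise mean over the remaining dates
  r2 <- r; r2[1, 1] <- NA
  comp <- monthly_composite(list(r, r2, r + 1), mask)
  expect_equal(comp[1, 1], mean(c(5, 6)))       # date 2 missing there
  expect_equal(comp[2, 2], mean(c(8, 8, 9)))
  # an extreme value in a long month is removed (mu +/- 3 sigma)
  rasters <- c(rep(list(r), 29), list(r * 0 + 100))
  comp2 <- monthly_composite(rasters, mask)
  expect_equal(comp2, r, tolerance = 1e-12)
})

test_that("spatial mean applies the trim and the coverage rule", {
  mask <- matrix(TRUE, 2, 5)
  # worked example: nine 10s and one 20 -> trimmed mean 10
  m <- matrix(c(rep(10, 9), 20), 2, 5)
  rec <- spatial_mean(m, mask)
  expect_equal(rec$fui, 10)
  expect_identical(rec$n_pixels_used, 9L)
  expect_true(rec$valid)
  # uniform raster: mean equals the value, full coverage
  u <- matrix(7, 2, 5)
  recu <- spatial_mean(u, mask)
  expect_equal(recu$fui, 7)
  expect_equal(recu$coverage, 1)
  # coverage at or below 30% -> invalid month
  low <- matrix(NA_real_, 2, 5); low[1, 1:2] <- 8   # coverage 0.2
  recl <- spatial_mean(low, mask)
  expect_false(recl$valid)
  expect_true(is.na(recl$fui))
})

test_that("validity rules enforce per-year month minima", {
  mk <- function(year, months, valid = TRUE)
    data.frame(year = year, month = months, fui = 8, valid = valid)
  # non-freezing lake with a 5-valid-month year is excluded entirely
  s <- rbind(mk(2001, 1:12), mk(2002, 1:5))
  out <- apply_validity_rules(s, freezing = FALSE)
  expect_false(out$lake_included)
  expect_identical(out$bad_years, 2002)
  # per-year dropping instead, behind the flag
  out2 <- apply_validity_rules(s, freezing = FALSE,
                               drop_lake_on_any_bad_year = FALSE)
  expect_true(out2$lake_included)
  expect_identical(sort(unique(out2$series$year)), 2001)
  # freezing lake: Nov-Apr removed before counting; 6 May-Oct months pass
  sf <- rbind(mk(2001, 1:12))
  outf <- apply_validity_rules(sf, freezing = TRUE)
  expect_true(outf$lake_included)
  expect_true(all(outf$series$month >= 5 & outf$series$month <= 10))
  # freezing lake with 2 valid May-Oct months is excluded
  sf2 <- rbind(data.frame(year = 2001, month = 5:10, fui = 8,
                          valid = c(TRUE, TRUE, rep(FALSE, 4))))
  expect_false(apply_validity_rules(sf2, freezing = TRUE)$lake_included)
})

test_that("gap filling is interior-only, linear and idempotent", {
  s <- data.frame(year = 2001, month = 1:3, fui = c(4, NA, 6))
  f <- fill_gaps(s)
  expect_equal(f$fui_filled, c(4, 5, 6))
  expect_identical(f$filled, c(FALSE, TRUE, FALSE))
  # two-gap linear fill on the month index
  s2 <- data.frame(year = 2001, month = 1:4, fui = c(4, NA, NA, 10))
  expect_equal(fill_gaps(s2)$fui_filled, c(4, 6, 8, 10))
  # leading/trailing gaps stay missing
  s3 <- data.frame(year = 2001, month = 1:4, fui = c(NA, 5, 6, NA))
  expect_equal(fill_gaps(s3)$fui_filled, c(NA, 5, 6, NA))
  # idempotent and never alters observed values
  f2 <- fill_gaps(transform(f, fui = fui_filled))
  expect_equal(f2$fui_filled, f$fui_filled)
  # freezing lakes: no interpolation across the winter break
  sf <- data.frame(year = rep(2001:2002, each = 6), month = rep(5:10, 2),
                   fui = c(5, rep(NA, 5), rep(NA, 5), 9))
  ff <- fill_gaps(sf, freezing = TRUE)
  expect_true(all(is.na(ff$fui_filled[2:11])))
})

test_that("yearly means and trends recover planted signals", {
  s <- data.frame(year = rep(2001, 6), month = 5:10,
                  fui_filled = c(6, 6, 7, 7, 8, 8))
  expect_equal(yearly_mean(s, 2001), 7)
  expect_true(is.na(yearly_mean(s, 2002)))
  # exact linear series -> slope 1, tiny p
  tr <- annual_trend(2001:2005, c(5, 6, 7, 8, 9))
  expect_equal(tr$slope, 1)
  expect_lt(tr$p_value, 1e-6)
  # constant series -> slope 0, not significant
  trc <- annual_trend(2001:2005, rep(4, 5))
  expect_equal(trc$slope, 0)
  expect_equal(trc$p_value, 1)
  expect_error(annual_trend(2001:2002, c(1, 2)), "3 years")
  # Monte-Carlo parameter recovery: slope 0.1/yr, noise sd 0.05, 19 yrs
  set.seed(41)
  slopes <- replicate(200, {
    y <- 8 + 0.1 * (0:18) + rnorm(19, 0, 0.05)
    annual_trend(2000:2018, y)$slope
  })
  expect_lt(abs(mean(slopes) - 0.1), 0.01)
  expect_true(all(slopes > 0))
  # Mann-Kendall alternative agrees on an obvious monotone series
  mk <- annual_trend(2000:2018, 5 + 0.2 * (0:18), method = "mann-kendall")
  expect_equal(mk$slope, 0.2, tolerance = 1e-9)
  expect_lt(mk$p_value, 0.01)
})

test_that("yearly series with planted outlier months keep the trend sign", {
  set.seed(42)
  hits <- replicate(100, {
    months <- expand.grid(month = 1:12, year = 2000:2018)
    f <- 8 + 0.1 * (months$year - 2000) +
      1.5 * sin(2 * pi * months$month / 12) + rnorm(nrow(months), 0, 0.3)
    out <- runif(nrow(months)) < 0.05
    f[out] <- f[out] + 6
    ym <- tapply(f, months$year, mean)
    annual_trend(as.integer(names(ym)), as.numeric(ym))$slope > 0
  })
  expect_gte(mean(hits), 0.95)
})
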