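test_that("look-up table invariants hold and recompute from chromaticity", {
  lut <- fui_lut()
  expect_true(validate_fui_lut(lut))
  # printed alpha + alpha_prime is exactly 270 in every row
  expect_identical(round(lut$alpha + lut$alpha_prime, 4), rep(270, 21))
  # hue angles recomputed from the printed 4-decimal chromaticities agree
  # with the printed angles to the 4-decimal rounding budget
  expect_lt(max(abs(hue_angle(lut$x, lut$y) - lut$alpha)), 0.05)
  expect_lt(max(abs(hue_angle_prime(lut$x, lut$y) - lut$alpha_prime)), 0.05)
  # shipped CSV is the same table
  csv <- read.csv(system.file("extdata", "fui_lut.csv", package = "lakeFUI"))
  expect_equal(csv, lut, tolerance = 1e-12)
})

test_that("rgb_to_xyz applies the printed linear map", {
  eq <- rgb_to_xyz(1, 1, 1)
  expect_equal(unlist(eq), c(X = 5.6508, Y = 5.6508, Z = 5.6508))
  expect_equal(unlist(rgb_to_xyz(1, 0, 0)), c(X = 2.7689, Y = 1, Z = 0))
  # linearity over seeded random triples
  set.seed(11)
  for (i in 1:20) {
    r <- runif(3, 0.001, 0.2)
    a <- rgb_to_xyz(r[1], r[2], r[3])
    b <- rgb_to_xyz(2 * r[1], 2 * r[2], 2 * r[3])
    expect_equal(unlist(b), 2 * unlist(a), tolerance = 1e-12)
  }
  expect_error(rgb_to_xyz(0, 0, 0), "all-zero")
  expect_error(rgb_to_xyz(-0.1, 0.2, 0.1), "non-negative")
})

test_that("xyz_to_xy normalises and is scale invariant", {
  expect_equal(xyz_to_xy(1, 1, 1), list(x = 1 / 3, y = 1 / 3))
  expect_equal(xyz_to_xy(2, 1, 1), list(x = 0.5, y = 0.25))
  set.seed(12)
  xyz <- runif(3, 0.1, 2)
  expect_equal(xyz_to_xy(xyz[1], xyz[2], xyz[3]),
               xyz_to_xy(7 * xyz[1], 7 * xyz[2], 7 * xyz[3]))
  expect_error(xyz_to_xy(0, 0, 0), "positive")
})

test_that("hue angle conventions behave and reject the white point", {
  expect_equal(hue_angle(1 / 3, 0.5), 90)
  expect_equal(hue_angle_prime(1 / 3, 0.5), 180)
  expect_error(hue_angle(1 / 3, 1 / 3), "white point")
  expect_error(hue_angle_prime(1 / 3, 1 / 3), "white point")
  # the two conventions sum to 270 below the 270-degree branch
  lut <- fui_lut()
  expect_equal(hue_angle(lut$x, lut$y) + hue_angle_prime(lut$x, lut$y),
               rep(270, 21), tolerance = 1e-9)
})

test_that("deviation polynomial matches an independent evaluation scheme", {
  expect_equal(delta_correction(0)$delta, 220.28)
  expect_equal(delta_correction(100)$delta, -20.7985, tolerance = 1e-9)
  # independent power-sum oracle vs the package's Horner evaluation
  power_sum <- function(alpha) {
    a <- alpha / 100
    -1.8185 * a^5 + 87.01 * a^4 - 486.65 * a^3 + 1004.93 * a^2 -
      844.55 * a + 220.28
  }
  for (a in c(0, 21.0471, 58.45, 100, 200, 229.533, 359)) {
    expect_equal(delta_correction(a)$delta, power_sum(a), tolerance = 1e-9)
    expect_equal(delta_correction(a)$alpha_corrected,
                 a + power_sum(a), tolerance = 1e-9)
  }
})

test_that("classify_fui is a clamped nearest-angle rule", {
  lut <- fui_lut()
  # every tabulated angle classifies to its own class
  expect_identical(classify_fui(lut$alpha), 1:21)
  # clamps
  expect_identical(classify_fui(300), 1L)
  expect_identical(classify_fui(229.5330), 1L)
  expect_identical(classify_fui(5), 21L)
  # nearest-neighbour against a brute-force oracle, midpoint tie -> lower
  nn_oracle <- function(a) {
    d <- abs(lut$alpha - a)
    which(d == min(d))[1]   # lower class index on ties
  }
  mid78 <- (118.5208 + 99.5371) / 2   # boundary between classes 7 and 8
  expect_identical(classify_fui(mid78 + 0.01), 7L)
  expect_identical(classify_fui(mid78), 7L)  # exact tie -> lower class
  set.seed(13)
  a <- runif(200, 15, 235)
  expect_identical(classify_fui(a),
                   vapply(a, nn_oracle, integer(1)))
  # monotone: larger angle never gives a larger class
  a_sorted <- sort(a, decreasing = TRUE)
  expect_true(all(diff(classify_fui(a_sorted)) >= 0))
  expect_identical(classify_fui(NaN), NA_integer_)
})

test_that("brightness scaling leaves chromaticity, hue and FUI unchanged", {
  set.seed(14)
  for (i in 1:50) {
    r <- runif(3, 0.005, 0.3)
    k <- runif(1, 0.1, 10)
    a <- rgb_to_xyz(r[1], r[2], r[3])
    b <- rgb_to_xyz(k * r[1], k * r[2], k * r[3])
    xya <- xyz_to_xy(a$X, a$Y, a$Z)
    xyb <- xyz_to_xy(b$X, b$Y, b$Z)
    expect_equal(xya, xyb, tolerance = 1e-12)
    expect_equal(classify_fui(hue_angle(xya$x, xya$y)),
                 classify_fui(hue_angle(xyb$x, xyb$y)))
  }
})

test_that("fui_image matches the scalar path pixelwise", {
  sp <- small_spec(fui = 5, noise_sd = 0)
  g <- generate_scene(sp)
  corr <- correct_water_leaving(g$scene)
  img <- fui_image(corr, g$truth$water_mask)
  # uniform class-5 lake classifies 5 everywhere in the mask
  expect_true(all(img[g$truth$water_mask] == 5L))
  # masked-out pixels carry NA
  expect_true(all(is.na(img[!g$truth$water_mask])))

  # mixed scene: raster path equals the per-pixel scalar computation
  sp2 <- scene_spec(c(60, 60), list(lake_spec(c(20, 20), 11, fui = 3),
                                    lake_spec(c(44, 42), 11, fui = 12)),
                    noise_sd = 0.002, seed = 9)
  g2 <- generate_scene(sp2)
  corr2 <- correct_water_leaving(g2$scene)
  img2 <- fui_image(corr2, g2$truth$water_mask)
  idx <- which(g2$truth$water_mask)
  scalar <- vapply(idx, function(i) {
    v <- c(red = corr2$bands$red[i], green = corr2$bands$green[i],
           blue = corr2$bands$blue[i], nir = 0, swir1640 = 0)
    forward_classify(v, apply_delta = TRUE)
  }, integer(1))
  expect_identical(img2[idx], scalar)
  # missing band is named in the rejection
  expect_error(fui_image(corr2, bands = c("red", "green", "magenta")),
               "magenta")
})
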