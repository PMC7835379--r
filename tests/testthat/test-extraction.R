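test_that("initial water mask follows the QA flags", {
  # all-land QA -> empty mask
  land <- scene_stack(as.Date("2001-07-04"),
                      bands = list(swir1640 = matrix(0.2, 10, 10)),
                      qa = matrix(0L, 10, 10))
  expect_false(any(initial_water_mask(land)))
  # synthetic lake QA -> mask equals truth
  g <- generate_scene(small_spec())
  expect_identical(initial_water_mask(g$scene), g$truth$water_mask)
  # half-clouded lake -> truth minus cloud pixels (set algebra on truth)
  gc <- generate_scene(small_spec(cloud_fraction = 0.4, seed = 6))
  cloud <- qa_flag(gc$scene$qa, "cloud")
  expect_identical(initial_water_mask(gc$scene),
                   gc$truth$water_mask & !cloud)
})

test_that("connected components respect 8-connectivity and the area floor", {
  m <- matrix(FALSE, 50, 80)
  # disc of about 120 px (30 km^2) and one of about 50 px (12.5 km^2)
  for (r in 1:50) for (c in 1:80) {
    if ((r - 20)^2 + (c - 20)^2 <= 6.2^2) m[r, c] <- TRUE   # ~120 px
    if ((r - 20)^2 + (c - 60)^2 <= 4^2) m[r, c] <- TRUE     # ~50 px
  }
  regs <- connected_components(m, pixel_size_m = 500, min_area_km2 = 25)
  expect_length(regs, 1L)
  expect_gte(regs[[1]]$area_km2, 25)
  # empty mask -> empty list
  expect_length(connected_components(matrix(FALSE, 5, 5)), 0L)
  # diagonal-touching blocks form one component under 8-connectivity
  d <- matrix(FALSE, 30, 30)
  d[2:11, 2:11] <- TRUE
  d[12:21, 12:21] <- TRUE
  regs_d <- connected_components(d, min_area_km2 = 0.1)
  expect_length(regs_d, 1L)
  expect_identical(sum(regs_d[[1]]$component_mask), 200L)
  # deterministic ordering by row-major first pixel
  two <- matrix(FALSE, 40, 40)
  two[30:36, 2:8] <- TRUE    # later in row-major order
  two[2:8, 30:36] <- TRUE    # first pixel earlier (row 2)
  regs2 <- connected_components(two, min_area_km2 = 0.1)
  expect_length(regs2, 2L)
  expect_true(regs2[[1]]$component_mask[2, 30])
  expect_true(regs2[[2]]$component_mask[30, 2])
})

test_that("buffer grows to 1.5 times the component area", {
  m <- matrix(FALSE, 60, 60)
  for (r in 1:60) for (c in 1:60)
    if ((r - 30)^2 + (c - 30)^2 <= 5.6^2) m[r, c] <- TRUE
  reg <- connected_components(m, min_area_km2 = 0.1)[[1]]
  comp_area <- sum(reg$component_mask)
  reg <- build_buffer(reg, factor = 1.5)
  expanded <- sum(reg$buffer_mask)
  # independent dilation oracle: grow ring by ring with a double loop
  grow_once <- function(x) {
    out <- x
    for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
      if (x[r, c]) next
      nb <- x[max(1, r - 1):min(nrow(x), r + 1),
              max(1, c - 1):min(ncol(x), c + 1)]
      if (any(nb)) out[r, c] <- TRUE
    }
    out
  }
  b <- reg$component_mask
  while (sum(b) < 1.5 * comp_area) b <- grow_once(b)
  expect_identical(expanded, sum(b))
  expect_gte(expanded, 1.5 * comp_area)
  # factor 1 leaves the component untouched
  reg1 <- build_buffer(connected_components(m, min_area_km2 = 0.1)[[1]],
                       factor = 1)
  expect_identical(reg1$buffer_mask, reg1$component_mask)
  # component against the grid edge: truncated buffer proceeds with warning
  edge <- matrix(FALSE, 12, 40)
  edge[1:12, 1:30] <- TRUE
  rege <- connected_components(edge, min_area_km2 = 0.1)[[1]]
  expect_warning(build_buffer(rege, factor = 1.5), "truncated")
})

test_that("threshold lands in the histogram valley with stated fallbacks", {
  set.seed(31)
  swir <- c(rnorm(4000, 0.02, 0.006), rnorm(3000, 0.20, 0.03))
  thr <- find_threshold(swir)
  # brute-force valley oracle on the same binning
  bw <- 0.002
  lo <- floor(min(swir) / bw) * bw
  breaks <- seq(lo, ceiling(max(swir) / bw) * bw, by = bw)
  counts <- hist(swir, breaks = breaks, plot = FALSE)$counts
  centres <- breaks[-length(breaks)] + bw / 2
  inw <- centres >= 0.04 & centres <= 0.12
  oracle <- centres[inw][which.min(counts[inw])]
  expect_equal(as.numeric(thr), oracle)
  expect_false(attr(thr, "fallback"))
  expect_gt(as.numeric(thr), 0.04)
  expect_lt(as.numeric(thr), 0.12)

  # regular grid over [0, 0.3]: flat counts, no valley -> midpoint
  expect_warning(thr2 <- find_threshold(seq(0, 0.3, by = 0.0005)),
                 "fallback")
  expect_equal(as.numeric(thr2), 0.08)
  expect_true(attr(thr2, "fallback"))

  # two equal-count minimum bins (0.061 and 0.091) -> lower wins
  centres <- seq(0.041, 0.119, by = 0.002)
  counts2 <- rep(10L, length(centres))
  counts2[abs(centres - 0.061) < 1e-9 | abs(centres - 0.091) < 1e-9] <- 2L
  vals <- c(rep(0.02, 80), rep(centres, counts2), rep(0.2, 80))
  thr3 <- find_threshold(vals)
  expect_equal(as.numeric(thr3), 0.061)

  # sample entirely outside the window -> fallback
  expect_warning(thr4 <- find_threshold(rep(0.2, 100)), "fallback")
  expect_equal(as.numeric(thr4), 0.08)
})

test_that("refine_lake applies threshold, QA, erosion and shallow rules", {
  sp <- small_spec(fui = 5, noise_sd = 0)
  g <- generate_scene(sp)
  reg <- connected_components(initial_water_mask(g$scene))[[1]]
  reg <- build_buffer(reg)
  reg <- suppressWarnings(refine_lake(g$scene, reg))
  expect_true(reg$observed)
  # noise-free lake: refined mask equals the truth mask eroded by 1 px
  expect_identical(reg$refined_mask, erode_oracle(g$truth$water_mask))
  # refined mask stays inside the expanded area, never on QA-flagged px
  expect_true(all(reg$buffer_mask[reg$refined_mask]))

  # fully cloud-flagged lake -> unobserved
  gcl <- generate_scene(sp)
  qa <- gcl$scene$qa
  qa[] <- bitwOr(qa, bitwShiftL(1L, qa_bits()[["cloud"]]))
  gcl$scene$qa <- qa
  regc <- suppressWarnings(
    refine_lake(gcl$scene,
                build_buffer(connected_components(
                  g$truth$water_mask)[[1]])))
  expect_false(regc$observed)
  expect_false(any(regc$refined_mask))

  # optically shallow rim (high blue) is excluded
  spsh <- scene_spec(c(60, 60),
                     list(lake_spec(c(30, 30), 12, fui = 5,
                                    shallow_margin_pixels = 2)),
                     noise_sd = 0, seed = 1)
  gsh <- generate_scene(spsh)
  regsh <- suppressWarnings(
    refine_lake(gsh$scene, build_buffer(connected_components(
      initial_water_mask(gsh$scene))[[1]])))
  expect_false(any(regsh$refined_mask & gsh$truth$shallow))
  # raising the shallow threshold never shrinks the refined mask
  reg_hi <- suppressWarnings(
    refine_lake(gsh$scene, build_buffer(connected_components(
      initial_water_mask(gsh$scene))[[1]]), shallow_blue = 0.5))
  expect_true(all(reg_hi$refined_mask | !regsh$refined_mask))
  expect_gt(sum(reg_hi$refined_mask), sum(regsh$refined_mask))
})

test_that("normal water mask uses occurrence over observable dates", {
  dims <- c(8, 8)
  wet <- matrix(FALSE, dims[1], dims[2]); wet[4, 4] <- TRUE
  dry <- matrix(FALSE, dims[1], dims[2])
  obs <- matrix(TRUE, dims[1], dims[2])
  # pixel water in 10 of 20 observable dates -> kept (0.5 > 0.3)
  nm <- normal_water_mask(c(rep(list(wet), 10), rep(list(dry), 10)),
                          rep(list(obs), 20))
  expect_true(nm$mask[4, 4])
  # ephemeral pond: 2 of 20 -> dropped
  nm2 <- normal_water_mask(c(rep(list(wet), 2), rep(list(dry), 18)),
                           rep(list(obs), 20))
  expect_false(any(nm2$mask))
  # unobservable dates are excluded from the denominator: water on 2 of
  # only 4 observable dates -> 0.5 > 0.3 -> kept
  blocked <- matrix(FALSE, dims[1], dims[2]); blocked[4, 4] <- TRUE
  nm3 <- normal_water_mask(
    c(rep(list(wet), 2), rep(list(dry), 18)),
    c(rep(list(obs), 4), rep(list(obs & !blocked), 16)))
  expect_true(nm3$mask[4, 4])
  # invariant to date ordering
  masks <- c(rep(list(wet), 10), rep(list(dry), 10))
  perm <- sample(20)
  nm4 <- normal_water_mask(masks[perm], rep(list(obs), 20))
  expect_identical(nm4$mask, nm$mask)
  # centroid in map coordinates through the affine transform
  sq <- matrix(FALSE, 10, 10); sq[3:4, 5:6] <- TRUE
  nm5 <- normal_water_mask(list(sq), transform = c(100, 900, 10))
  xy <- pixel_to_xy(c(100, 900, 10), 3.5, 5.5)   # centre of the square
  expect_equal(nm5$centroid_x, xy$x)
  expect_equal(nm5$centroid_y, xy$y)
  expect_equal(nm5$area_km2, 4 * 0.25)
})

test_that("refined masks track truth within the erosion allowance", {
  # dilating the refined mask back by one pixel recovers the truth disc
  for (seed in c(2, 7)) {
    g <- generate_scene(small_spec(fui = 7, noise_sd = 0, seed = seed))
    reg <- suppressWarnings(
      refine_lake(g$scene, build_buffer(connected_components(
        initial_water_mask(g$scene))[[1]])))
    redil <- dilate3(reg$refined_mask)
    iou <- sum(redil & g$truth$water_mask) / sum(redil | g$truth$water_mask)
    expect_gte(iou, 0.9)
  }
})
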