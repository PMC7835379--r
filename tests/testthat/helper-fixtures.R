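# Shared fixtures, built in code at test time.

# one-pixel scene with given band values
px_scene <- function(red, green, blue, nir, swir,
                     qa = 0L, date = as.Date("2001-07-04")) {
  scene_stack(date,
              bands = list(red = matrix(red), green = matrix(green),
                           blue = matrix(blue), nir = matrix(nir),
                           swir1640 = matrix(swir)),
              qa = matrix(as.integer(qa)))
}

# default small lake world: one disc lake on a 60x60 grid
small_spec <- function(fui = 5, cloud_fraction = 0, seed = 1,
                       noise_sd = 0.001, ...) {
  scene_spec(c(60, 60), list(lake_spec(c(30, 30), 12, fui = fui)),
             cloud_fraction = cloud_fraction, noise_sd = noise_sd,
             seed = seed, ...)
}

# independent 3x3 erosion oracle (double loop, border treated as FALSE)
erode_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c]) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !m[rr, cc]) ok <- FALSE
    }
    out[r, c] <- ok
  }
  out
}

# independent forward classification of a 5-band reflectance vector:
# min NIR-SWIR subtraction, colorimetry, optional deviation correction
forward_classify <- function(v, apply_delta = FALSE) {
  mn <- min(v[["nir"]], v[["swir1640"]])
  rgb <- v[c("red", "green", "blue")] - mn
  xyz <- rgb_to_xyz(rgb[1], rgb[2], rgb[3])
  xy <- xyz_to_xy(xyz$X, xyz$Y, xyz$Z)
  a <- hue_angle(xy$x, xy$y)
  if (apply_delta) a <- delta_correction(a)$alpha_corrected
  classify_fui(a)
}
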