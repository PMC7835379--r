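# Per-pixel FUI retrieval: corrected R, G, B reflectance -> CIE tristimulus
# -> chromaticity -> hue angle -> band-setting deviation correction ->
# 21-class look-up. All functions are vectorised over pixels.

# RGB -> XYZ conversion matrix for broad-band red/green/blue reflectance.
.RGB2XYZ <- rbind(
  X = c(R = 2.7689, G = 1.7517, B = 1.1302),
  Y = c(R = 1.0000, G = 4.5907, B = 0.0601),
  Z = c(R = 0.0000, G = 0.0565, B = 5.5943)
)

# Coefficients of the deviation polynomial in a = alpha/100, highest
# degree first. Models the hue-angle offset between human-eye-sensed true
# colour and the colour reconstructed from the satellite's broad bands.
.DELTA_COEF <- c(-1.8185, 87.01, -486.65, 1004.93, -844.55, 220.28)

#' Convert red/green/blue reflectance to CIE tristimulus values
#'
#' Applies the fixed linear transform
#' \deqn{X = 2.7689R + 1.7517G + 1.1302B}
#' \deqn{Y = 1.00R + 4.5907G + 0.0601B}
#' \deqn{Z = 0.00R + 0.0565G + 5.5943B}
#' mapping broad-band reflectance in the satellite's red, green and blue
#' bands to CIE 1931 tristimulus values.
#'
#' @param R,G,B Numeric vectors of non-negative reflectance (recycled to a
#'   common length).
#' @return A list with numeric components `X`, `Y`, `Z`.
#' @export
#' @examples
#' rgb_to_xyz(1, 1, 1) # X = Y = Z = 5.6508
rgb_to_xyz <- function(R, G, B) {
  n <- max(length(R), length(G), length(B))
  R <- rep_len(as.numeric(R), n)
  G <- rep_len(as.numeric(G), n)
  B <- rep_len(as.numeric(B), n)
  bad <- !is.na(R) & !is.na(G) & !is.na(B) & (R < 0 | G < 0 | B < 0)
  if (any(bad))
    stop("reflectance must be non-negative")
  zero <- !is.na(R) & !is.na(G) & !is.na(B) & R == 0 & G == 0 & B == 0
  if (any(zero))
    stop("all-zero (R, G, B): chromaticity undefined")
  m <- .RGB2XYZ
  list(
    X = m["X", "R"] * R + m["X", "G"] * G + m["X", "B"] * B,
    Y = m["Y", "R"] * R + m["Y", "G"] * G + m["Y", "B"] * B,
    Z = m["Z", "R"] * R + m["Z", "G"] * G + m["Z", "B"] * B
  )
}

#' Tristimulus to chromaticity coordinates
#'
#' Brightness-normalises CIE tristimulus values:
#' `x = X/(X+Y+Z)`, `y = Y/(X+Y+Z)`.
#'
#' @param X,Y,Z Numeric vectors of tristimulus values with `X+Y+Z > 0`.
#' @return A list with numeric components `x`, `y`.
#' @export
xyz_to_xy <- function(X, Y, Z) {
  s <- X + Y + Z
  if (any(!is.na(s) & s <= 0))
    stop("X + Y + Z must be positive")
  list(x = X / s, y = Y / s)
}

#' Chromaticity hue angle (anticlockwise convention)
#'
#' Angle of the chromaticity point around the white point (1/3, 1/3),
#' measured anticlockwise in degrees from the positive x-axis:
#' `alpha = (atan2(y - 1/3, x - 1/3) mod 2*pi) * 180/pi`, in `[0, 360)`.
#'
#' @param x,y Chromaticity coordinates.
#' @return Hue angle in degrees.
#' @seealso [hue_angle_prime()] for the legacy clockwise convention.
#' @export
#' @examples
#' hue_angle(1/3, 0.5) # 90
hue_angle <- function(x, y) {
  dx <- x - 1 / 3
  dy <- y - 1 / 3
  at_white <- !is.na(dx) & !is.na(dy) &
    abs(dx) < 1e-12 & abs(dy) < 1e-12   # numerically achromatic
  if (any(at_white))
    stop("hue angle undefined at the white point (1/3, 1/3)")
  (atan2(dy, dx) %% (2 * pi)) * 180 / pi
}

#' Chromaticity hue angle (legacy clockwise convention)
#'
#' The alternative convention used in earlier water-colour work:
#' `alpha_prime = (atan2(x - 1/3, y - 1/3) + pi)` in degrees, increasing
#' clockwise from the negative y-axis, so that it increases with FUI class.
#' For the colour locus it relates to [hue_angle()] by
#' `alpha + alpha_prime = 270` (mod 360).
#'
#' @inheritParams hue_angle
#' @return Hue angle in degrees in `[0, 360)`.
#' @export
hue_angle_prime <- function(x, y) {
  dx <- x - 1 / 3
  dy <- y - 1 / 3
  at_white <- !is.na(dx) & !is.na(dy) &
    abs(dx) < 1e-12 & abs(dy) < 1e-12
  if (any(at_white))
    stop("hue angle undefined at the white point (1/3, 1/3)")
  ((atan2(dx, dy) + pi) %% (2 * pi)) * 180 / pi
}

#' Hue-angle deviation correction for the satellite band setting
#'
#' The hue angle reconstructed from three broad visible bands is
#' systematically offset from the true-colour hue angle. The offset is
#' modelled as a degree-5 polynomial in `a = alpha/100`:
#' \deqn{\Delta = -1.8185 a^5 + 87.01 a^4 - 486.65 a^3 + 1004.93 a^2
#'       - 844.55 a + 220.28}
#' and the corrected angle is `alpha + Delta`. The correction applies to
#' satellite-derived angles only; true-colour chromaticities (look-up
#' table points, hyperspectrally resampled field spectra) must be
#' classified without it.
#'
#' @param alpha Hue angle(s) in degrees in `[0, 360)`.
#' @return A list with components `delta` and `alpha_corrected`
#'   (`alpha + delta`), both in degrees.
#' @export
#' @examples
#' delta_correction(0)$delta   # 220.28
#' delta_correction(100)$delta # -20.7985
delta_correction <- function(alpha) {
  a <- alpha / 100
  # Horner form of the printed coefficients
  d <- .DELTA_COEF[1]
  for (cf in .DELTA_COEF[-1]) d <- d * a + cf
  list(delta = d, alpha_corrected = alpha + d)
}

#' Classify a corrected hue angle into a Forel-Ule class
#'
#' Nearest-neighbour classification against the 21 look-up-table hue
#' angles: the class whose tabulated `alpha` is closest to
#' `alpha_corrected` wins; angles above the class-1 angle (229.5330)
#' clamp to 1, below the class-21 angle (21.0471) clamp to 21; exact ties
#' go to the lower class index (the bluer class). Since the tabulated
#' angles are strictly decreasing, this is identical to interval-midpoint
#' boundaries.
#'
#' @param alpha_corrected Numeric vector of corrected hue angles (degrees).
#' @param lut Look-up table, see [fui_lut()].
#' @return Integer vector of FUI classes in `1..21`; `NA` for non-finite
#'   input.
#' @export
classify_fui <- function(alpha_corrected, lut = fui_lut()) {
  validate_fui_lut(lut)
  a <- as.numeric(alpha_corrected)
  out <- rep(NA_integer_, length(a))
  ok <- is.finite(a)
  if (!any(ok)) return(out)
  av <- a[ok]
  # boundaries between consecutive classes: midpoints of decreasing alphas
  mid <- (lut$alpha[-21] + lut$alpha[-1]) / 2    # length 20, decreasing
  # class k iff alpha in (mid[k], mid[k-1]]; exact midpoint ties -> lower k
  cls <- rep(1L, length(av))
  for (k in 1:20) cls <- cls + (av < mid[k])     # strict: tie stays at k
  out[ok] <- cls
  out
}

#' Per-pixel Forel-Ule classification of a scene
#'
#' Runs the full colorimetric chain (tristimulus, chromaticity, hue angle,
#' optional deviation correction, look-up) on the red/green/blue bands of
#' an already water-leaving-corrected scene, inside a mask.
#'
#' @param scene A [scene_stack] whose visible bands are already corrected.
#' @param mask Logical matrix of the scene's grid shape; pixels outside
#'   the mask (or `NA`/flagged inside it) are returned as `NA`.
#' @param lut Look-up table, see [fui_lut()].
#' @param apply_delta Apply the satellite band-setting correction
#'   ([delta_correction()]) before classification. Use `TRUE` (default)
#'   for satellite scenes and `FALSE` for true-colour inputs.
#' @param bands Character vector naming the red, green and blue bands in
#'   `scene$bands`, in that order.
#' @return Integer matrix of FUI classes (`NA` where invalid).
#' @export
fui_image <- function(scene, mask = NULL, lut = fui_lut(),
                      apply_delta = TRUE,
                      bands = c("red", "green", "blue")) {
  stopifnot(inherits(scene, "scene_stack"), length(bands) == 3)
  missing <- setdiff(bands, names(scene$bands))
  if (length(missing))
    stop("scene is missing band(s): ", paste(missing, collapse = ", "))
  R <- scene$bands[[bands[1]]]
  G <- scene$bands[[bands[2]]]
  B <- scene$bands[[bands[3]]]
  dims <- dim(R)
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  stopifnot(identical(dim(mask), dims))

  out <- matrix(NA_integer_, dims[1], dims[2])
  idx <- which(mask & is.finite(R) & is.finite(G) & is.finite(B) &
                 R >= 0 & G >= 0 & B >= 0 & (R + G + B > 0))
  if (!length(idx)) return(out)
  xyz <- rgb_to_xyz(R[idx], G[idx], B[idx])
  xy <- xyz_to_xy(xyz$X, xyz$Y, xyz$Z)
  # white-point pixels have no hue: drop rather than error in raster path
  at_white <- abs(xy$x - 1 / 3) < 1e-12 & abs(xy$y - 1 / 3) < 1e-12
  if (any(at_white)) {
    idx <- idx[!at_white]
    xy$x <- xy$x[!at_white]
    xy$y <- xy$y[!at_white]
    if (!length(idx)) return(out)
  }
  alpha <- hue_angle(xy$x, xy$y)
  if (apply_delta) alpha <- delta_correction(alpha)$alpha_corrected
  out[idx] <- classify_fui(alpha, lut)
  out
}
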