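# scene_stack: one dated multiband reflectance raster with a QA bitmask
# and a simple affine georeference. Bands are plain numeric matrices
# (rows = north-to-south scan lines, cols = west-to-east).

# QA bit positions (bit 0 = least significant)
.QA_BITS <- c(cloud = 0L, cloud_shadow = 1L, snow_ice = 2L,
              inland_water = 3L, mixed = 4L, other_noise = 5L)

#' QA bitmask flag positions
#'
#' Named integer vector giving the bit position (0-based) of each
#' per-pixel quality flag in the QA band: `cloud`, `cloud_shadow`,
#' `snow_ice`, `inland_water`, `mixed`, `other_noise`.
#'
#' @return Named integer vector.
#' @export
qa_bits <- function() .QA_BITS

#' Test QA flags on a QA raster
#'
#' @param qa Integer matrix (QA bitmask band).
#' @param flags Character vector of flag names among `names(qa_bits())`.
#' @return Logical matrix, `TRUE` where any of the named bits is set.
#' @export
qa_flag <- function(qa, flags) {
  bad <- setdiff(flags, names(.QA_BITS))
  if (length(bad))
    stop("unknown QA flag(s): ", paste(bad, collapse = ", "))
  out <- matrix(FALSE, nrow(qa), ncol(qa))
  for (f in flags)
    out <- out | (bitwAnd(qa, bitwShiftL(1L, .QA_BITS[[f]])) != 0L)
  out
}

#' Observation-blocking QA mask
#'
#' Pixels where cloud, cloud shadow, snow/ice, mixed-pixel or other-noise
#' bits are set — i.e. pixels that carry no usable water observation.
#'
#' @inheritParams qa_flag
#' @return Logical matrix, `TRUE` where the pixel is unusable.
#' @export
qa_blocked <- function(qa) {
  qa_flag(qa, c("cloud", "cloud_shadow", "snow_ice", "mixed", "other_noise"))
}

#' Construct a scene stack
#'
#' A `scene_stack` holds one dated multiband reflectance raster: a named
#' list of band matrices (all the same shape), an integer QA bitmask
#' matrix (see [qa_bits()]), and a minimal georeference (affine transform
#' of the north-west corner plus a square cell size, and a CRS label).
#'
#' @param date A `Date` (the composite's nominal date).
#' @param bands Named list of numeric matrices, all the same dimension.
#'   Conventional names: `red`, `green`, `blue`, `nir`, `swir1640`.
#' @param qa Integer matrix of QA bit flags, same dimension as the bands.
#' @param transform Numeric vector `c(x0, y0, cell)`: x/y of the *outer
#'   north-west corner* and the square cell size, in CRS units. Pixel
#'   (row r, col c) has centre `(x0 + (c - 0.5) cell, y0 - (r - 0.5) cell)`.
#' @param crs CRS label (free text, carried through unchanged).
#' @param pixel_size_m Ground pixel size in metres (used for areas).
#' @return An object of class `scene_stack`.
#' @export
scene_stack <- function(date, bands, qa,
                        transform = c(0, 0, 1), crs = "local",
                        pixel_size_m = 500) {
  stopifnot(inherits(date, "Date"), length(date) == 1L,
            is.list(bands), length(bands) >= 1L,
            !is.null(names(bands)), all(nzchar(names(bands))))
  dims <- dim(bands[[1]])
  for (nm in names(bands)) {
    if (!is.matrix(bands[[nm]]) || !identical(dim(bands[[nm]]), dims))
      stop("band '", nm, "' does not match the grid shape")
  }
  if (!identical(dim(qa), dims))
    stop("QA band does not match the grid shape")
  storage.mode(qa) <- "integer"
  stopifnot(is.numeric(transform), length(transform) == 3L, transform[3] > 0)
  structure(
    list(date = date, bands = bands, qa = qa,
         transform = as.numeric(transform), crs = crs,
         pixel_size_m = as.numeric(pixel_size_m)),
    class = "scene_stack"
  )
}

#' @export
print.scene_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat("<scene_stack> ", format(x$date), "  ", d[1], "x", d[2],
      " px, bands: ", paste(names(x$bands), collapse = ", "),
      "\n  transform: NW corner (", x$transform[1], ", ", x$transform[2],
      "), cell ", x$transform[3], " [", x$crs, "], pixel ",
      x$pixel_size_m, " m\n", sep = "")
  invisible(x)
}

#' Map pixel centres to map coordinates
#'
#' @param transform Affine transform `c(x0, y0, cell)` as stored in a
#'   [scene_stack()].
#' @param row,col Pixel indices (1-based, recycled).
#' @return A list with numeric components `x` and `y` of pixel centres.
#' @export
pixel_to_xy <- function(transform, row, col) {
  list(x = transform[1] + (col - 0.5) * transform[3],
       y = transform[2] - (row - 0.5) * transform[3])
}

#' Map map coordinates to the nearest pixel
#'
#' @inheritParams pixel_to_xy
#' @param x,y Map coordinates.
#' @return A list with integer components `row` and `col` (may fall
#'   outside the grid; callers must range-check).
#' @export
xy_to_pixel <- function(transform, x, y) {
  list(row = as.integer(ceiling((transform[2] - y) / transform[3])),
       col = as.integer(ceiling((x - transform[1]) / transform[3])))
}
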