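# Water-leaving reflectance correction. Surface reflectance over water
# still contains skylight reflection, residual aerosol and sun glint;
# over clear-to-turbid inland water these contributions are spectrally
# near-flat while the water-leaving signal in the NIR-SWIR is close to
# zero, so the per-pixel minimum across the NIR-SWIR bands estimates the
# additive offset and is subtracted from every band.

#' Water-leaving reflectance correction by minimum NIR-SWIR subtraction
#'
#' For each pixel, the minimum reflectance across the named NIR-SWIR
#' bands is subtracted from all bands. The operation is translation
#' invariant (adding a constant to all bands of a pixel does not change
#' the corrected visible bands) and idempotent on pixels whose NIR-SWIR
#' minimum is already zero.
#'
#' Negative post-correction values are unphysical and are clamped to 0;
#' clamped pixels are flagged in the returned scene's `clamped` matrix.
#' Pixels whose red, green and blue bands are all 0 after clamping have
#' undefined chromaticity and are flagged in `invalid_rgb`.
#'
#' @param scene A [scene_stack].
#' @param nir_swir Character vector of NIR-SWIR band names (non-empty).
#' @param visible Character vector naming the red/green/blue bands (used
#'   only for the `invalid_rgb` flag).
#' @return The corrected `scene_stack` with logical matrices `clamped`
#'   and `invalid_rgb` attached; QA is propagated unchanged.
#' @export
#' @examples
#' # one pixel: visible (0.05, 0.06, 0.04), NIR-SWIR min 0.010
#' sc <- scene_stack(as.Date("2001-01-01"),
#'   bands = list(red = matrix(0.05), green = matrix(0.06),
#'                blue = matrix(0.04), nir = matrix(0.012),
#'                swir1640 = matrix(0.010)),
#'   qa = matrix(0L))
#' out <- correct_water_leaving(sc)
#' unlist(lapply(out$bands[c("red", "green", "blue")], as.vector))
correct_water_leaving <- function(scene,
                                  nir_swir = c("nir", "swir1640"),
                                  visible = c("red", "green", "blue")) {
  stopifnot(inherits(scene, "scene_stack"))
  if (!length(nir_swir))
    stop("nir_swir band list must be non-empty")
  missing <- setdiff(nir_swir, names(scene$bands))
  if (length(missing))
    stop("scene is missing NIR-SWIR band(s): ",
         paste(missing, collapse = ", "))

  mn <- scene$bands[[nir_swir[1]]]
  for (nm in nir_swir[-1]) mn <- pmin(mn, scene$bands[[nm]])

  clamped <- matrix(FALSE, nrow(mn), ncol(mn))
  out_bands <- scene$bands
  for (nm in names(out_bands)) {
    v <- out_bands[[nm]] - mn
    neg <- !is.na(v) & v < 0
    clamped <- clamped | neg
    v[neg] <- 0
    out_bands[[nm]] <- v
  }

  out <- scene
  out$bands <- out_bands
  out$clamped <- clamped

  vis <- intersect(visible, names(out_bands))
  if (length(vis) == 3L) {
    s <- out_bands[[vis[1]]] + out_bands[[vis[2]]] + out_bands[[vis[3]]]
    out$invalid_rgb <- !is.na(s) & s == 0
  } else {
    out$invalid_rgb <- matrix(FALSE, nrow(mn), ncol(mn))
  }
  out
}
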