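# The 21-class Forel-Ule colour look-up table: CIE 1931 chromaticity
# coordinates of the dyed colour standards and the two hue-angle
# conventions in use (alpha anticlockwise from the positive x-axis,
# alpha_prime clockwise from the negative y-axis; alpha + alpha_prime = 270).

.FUI_LUT <- data.frame(
  fui = 1:21,
  x = c(0.1914, 0.1990, 0.2100, 0.2265, 0.2459, 0.2662, 0.2908,
        0.3154, 0.3367, 0.3633, 0.3862, 0.4024, 0.4162, 0.4313,
        0.4457, 0.4606, 0.4753, 0.4887, 0.5033, 0.5155, 0.5283),
  y = c(0.1669, 0.1999, 0.2399, 0.2883, 0.3353, 0.3762, 0.4115,
        0.4400, 0.4617, 0.4764, 0.4866, 0.4811, 0.4737, 0.4655,
        0.4576, 0.4494, 0.4410, 0.4328, 0.4246, 0.4161, 0.4083),
  alpha = c(229.5330, 224.8037, 217.1473, 202.8305, 178.7020, 147.4148,
            118.5208, 99.5371, 88.5017, 78.1648, 70.9617, 64.9378,
            59.4234, 53.4431, 47.8847, 42.3707, 37.1698, 32.6477,
            28.2408, 24.4487, 21.0471),
  alpha_prime = c(40.4670, 45.1963, 52.8527, 67.1695, 91.2980, 122.5852,
                  151.4792, 170.4629, 181.4983, 191.8352, 199.0383,
                  205.0622, 210.5766, 216.5569, 222.1153, 227.6293,
                  232.8302, 237.3523, 241.7592, 245.5513, 248.9529)
)

#' Forel-Ule look-up table
#'
#' Returns the 21-class Forel-Ule colour standard table: CIE 1931
#' chromaticity coordinates `(x, y)` of each class and the corresponding
#' hue angles in the two conventions, `alpha` (degrees, anticlockwise from
#' the positive x-axis around the white point) and `alpha_prime` (degrees,
#' clockwise convention used in earlier work). `alpha + alpha_prime = 270`
#' for every class. Class 1 is dark blue, class 21 yellowish-brown.
#'
#' The same table is shipped as a plain CSV at
#' `system.file("extdata", "fui_lut.csv", package = "lakeFUI")`.
#'
#' @return A data frame with columns `fui`, `x`, `y`, `alpha`, `alpha_prime`.
#' @export
#' @examples
#' lut <- fui_lut()
#' stopifnot(nrow(lut) == 21, all(lut$alpha + lut$alpha_prime == 270))
fui_lut <- function() {
  .FUI_LUT
}

#' Validate a Forel-Ule look-up table
#'
#' Checks the structural invariants of a FUI look-up table: 21 rows,
#' `alpha` strictly decreasing with class, `alpha_prime` strictly
#' increasing, `alpha + alpha_prime == 270` and `x + y < 1` in every row.
#'
#' @param lut A data frame as returned by [fui_lut()].
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_fui_lut <- function(lut) {
  stopifnot(is.data.frame(lut))
  need <- c("fui", "x", "y", "alpha", "alpha_prime")
  missing <- setdiff(need, names(lut))
  if (length(missing))
    stop("look-up table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(lut) != 21L || !identical(as.integer(lut$fui), 1:21))
    stop("look-up table must have classes 1..21 in order")
  if (any(diff(lut$alpha) >= 0))
    stop("alpha must be strictly decreasing with FUI class")
  if (any(diff(lut$alpha_prime) <= 0))
    stop("alpha_prime must be strictly increasing with FUI class")
  if (any(abs(lut$alpha + lut$alpha_prime - 270) > 1e-9))
    stop("alpha + alpha_prime must equal 270 in every row")
  if (any(lut$x + lut$y >= 1))
    stop("chromaticity must satisfy x + y < 1")
  invisible(TRUE)
}
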