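# Binary morphology and connected-component labelling on logical
# matrices. The structuring element is the 3x3 square (8-neighbourhood,
# one ring = one native pixel), which at 500 m resolution realises the
# 500 m shoreline buffer used against land adjacency.

# Shift a matrix by (dr, dc), padding with `fill`.
.shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.NBR8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Dilate a binary mask by one 3x3 ring
#'
#' @param mask Logical matrix.
#' @return Logical matrix: `mask` grown by its 8-neighbourhood.
#' @export
dilate3 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(.NBR8)))
    out <- out | .shift_mat(mask, .NBR8[i, 1], .NBR8[i, 2], FALSE)
  out
}

#' Erode a binary mask by one 3x3 ring
#'
#' Pixels on the grid border are eroded (treated as facing FALSE outside).
#'
#' @param mask Logical matrix.
#' @return Logical matrix: `mask` shrunk by its 8-neighbourhood.
#' @export
erode3 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(.NBR8)))
    out <- out & .shift_mat(mask, .NBR8[i, 1], .NBR8[i, 2], FALSE)
  out
}

#' Label connected components of a binary mask
#'
#' 8-connectivity labelling by iterative minimum-label propagation
#' (vectorised; converges in at most the maximal geodesic diameter of a
#' component). Labels are renumbered 1..k in row-major order of each
#' component's first pixel, which fixes a deterministic component order.
#'
#' @param mask Logical matrix.
#' @return Integer matrix: 0 for background, 1..k component labels.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  lab[mask] <- seq_len(sum(mask))
  idx <- matrix(0L, nr, nc)
  idx[mask] <- lab[mask]
  cur <- matrix(Inf, nr, nc)
  cur[mask] <- idx[mask]
  repeat {
    nxt <- cur
    for (i in seq_len(nrow(.NBR8))) {
      sh <- .shift_mat(cur, .NBR8[i, 1], .NBR8[i, 2], Inf)
      nxt <- pmin(nxt, sh)
    }
    nxt[!mask] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  raw <- cur
  raw[!mask] <- 0
  # renumber in row-major order of first appearance
  labs <- unique(as.vector(t(raw))[as.vector(t(mask))])
  out <- matrix(0L, nr, nc)
  for (k in seq_along(labs)) out[raw == labs[k]] <- k
  out
}
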