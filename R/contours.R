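#' @include grid.R
NULL

# even-odd (crossing number) point-in-polygon, vectorized over points.
# px, py: point coordinates; polygon given by vertex vectors vx, vy
# (implicitly closed). Points exactly on an edge follow the half-open
# crossing rule, which keeps adjacent polygons non-overlapping.
.pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (n >= 2L && vx[1L] == vx[n] && vy[1L] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L   # drop explicit closure
  }
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xin <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) /
             (vy[j] - vy[i]) + vx[i]
      hit <- px[crosses] < xin
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

#' Rasterize a stack of planar contours into a binary mask
#'
#' Each contour is a closed polygon lying on one axial plane. A voxel is set
#' iff its center lies inside the polygon of its slice by the even-odd rule;
#' multiple polygons that land on the same slice are XOR-combined, which
#' represents holes (e.g. a ring as outer polygon + inner polygon).
#'
#' @param contours list of contours, each a list with elements `z` (mm plane
#'   position), `x`, `y` (mm vertex coordinates of a closed polygon; the
#'   closing vertex may be repeated or left implicit).
#' @param grid target [VoxelGrid].
#' @return a [BinaryMask] on `grid`.
#' @details Contours whose plane lies further than half a slice spacing from
#'   the nearest grid slice are skipped with a warning.
#' @examples
#' g <- makeGrid(c(16, 16, 4), 2.0)
#' sq <- list(z = origin(g)[3], x = c(-5, 5, 5, -5), y = c(-5, -5, 5, 5))
#' voxelCount(rasterizePolygonStack(list(sq), g))  # 25 voxel centers inside
#' @export
rasterizePolygonStack <- function(contours, grid) {
  vals <- array(FALSE, grid@shape)
  if (length(contours) == 0L) return(binaryMask(vals, grid))
  cx <- .axisCenters(grid, 1L)
  cy <- .axisCenters(grid, 2L)
  cz <- .axisCenters(grid, 3L)
  px <- rep(cx, times = grid@shape[2L])
  py <- rep(cy, each = grid@shape[1L])
  for (ct in contours) {
    if (is.null(ct$z) || is.null(ct$x) || is.null(ct$y))
      stop("each contour needs elements z, x, y")
    k <- which.min(abs(cz - ct$z))
    if (abs(cz[k] - ct$z) > grid@spacing[3L] / 2 + 1e-9) {
      warning(sprintf(
        "contour at z = %.2f mm lies outside the grid slices; skipped",
        ct$z))
      next
    }
    inside <- .pointsInPolygon(px, py, as.numeric(ct$x), as.numeric(ct$y))
    slice <- matrix(inside, grid@shape[1L], grid@shape[2L])
    vals[, , k] <- xor(vals[, , k], slice)
  }
  binaryMask(vals, grid)
}
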