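#' @include grid.R
NULL

#' Resample a binary mask onto another grid (nearest neighbor)
#'
#' Each target voxel takes the occupancy of the source voxel whose center is
#' nearest to the target voxel center in patient coordinates; target centers
#' outside the source extent become 0. Identity when the grids are identical.
#'
#' @param mask a [BinaryMask].
#' @param targetGrid a [VoxelGrid].
#' @return a [BinaryMask] on `targetGrid`.
#' @export
resampleMask <- function(mask, targetGrid) {
  src <- mask@grid
  if (sameGrid(src, targetGrid)) return(mask)
  idx <- lapply(1:3, function(a) {
    tc <- .axisCenters(targetGrid, a)
    i <- as.integer(round((tc - src@origin[a]) / src@spacing[a])) + 1L
    i[i < 1L | i > src@shape[a]] <- NA_integer_
    i
  })
  out <- array(FALSE, targetGrid@shape)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  if (any(ok1) && any(ok2) && any(ok3))
    out[ok1, ok2, ok3] <-
      mask@values[idx[[1]][ok1], idx[[2]][ok2], idx[[3]][ok3]]
  binaryMask(out, targetGrid)
}

# fractional source index (1-based) of target centers along one axis,
# clamped to the source extent for edge extrapolation-free interpolation
.fracIndex <- function(targetGrid, srcGrid, a) {
  tc <- .axisCenters(targetGrid, a)
  f <- (tc - srcGrid@origin[a]) / srcGrid@spacing[a] + 1
  pmin(pmax(f, 1), srcGrid@shape[a])
}

#' Resample a dose grid onto another grid (trilinear)
#'
#' Standard separable trilinear interpolation at target voxel centers;
#' target centers outside the source extent are clamped to the boundary.
#'
#' @param dose a [DoseGrid].
#' @param targetGrid a [VoxelGrid].
#' @return a [DoseGrid] on `targetGrid`.
#' @export
resampleDose <- function(dose, targetGrid) {
  src <- dose@grid
  if (sameGrid(src, targetGrid)) return(dose)
  f1 <- .fracIndex(targetGrid, src, 1L)
  f2 <- .fracIndex(targetGrid, src, 2L)
  f3 <- .fracIndex(targetGrid, src, 3L)
  lo1 <- pmin(floor(f1), src@shape[1L] - 1L); w1 <- f1 - lo1
  lo2 <- pmin(floor(f2), src@shape[2L] - 1L); w2 <- f2 - lo2
  lo3 <- pmin(floor(f3), src@shape[3L] - 1L); w3 <- f3 - lo3
  if (src@shape[1L] == 1L) { lo1 <- rep(1, length(f1)); w1 <- w1 * 0 }
  if (src@shape[2L] == 1L) { lo2 <- rep(1, length(f2)); w2 <- w2 * 0 }
  if (src@shape[3L] == 1L) { lo3 <- rep(1, length(f3)); w3 <- w3 * 0 }
  sh <- targetGrid@shape
  n <- prod(sh)
  I1 <- rep(lo1, times = sh[2L] * sh[3L])
  W1 <- rep(w1, times = sh[2L] * sh[3L])
  I2 <- rep(rep(lo2, each = sh[1L]), times = sh[3L])
  W2 <- rep(rep(w2, each = sh[1L]), times = sh[3L])
  I3 <- rep(lo3, each = sh[1L] * sh[2L])
  W3 <- rep(w3, each = sh[1L] * sh[2L])
  d <- dose@dose
  n1 <- src@shape[1L]; n12 <- n1 * src@shape[2L]
  corner <- function(a, b, c)
    d[(I1 + a) + (I2 + b - 1) * n1 + (I3 + c - 1) * n12]
  up1 <- as.integer(src@shape[1L] > 1L)
  up2 <- as.integer(src@shape[2L] > 1L)
  up3 <- as.integer(src@shape[3L] > 1L)
  out <-
    corner(0,   0,   0  ) * (1 - W1) * (1 - W2) * (1 - W3) +
    corner(up1, 0,   0  ) * W1       * (1 - W2) * (1 - W3) +
    corner(0,   up2, 0  ) * (1 - W1) * W2       * (1 - W3) +
    corner(up1, up2, 0  ) * W1       * W2       * (1 - W3) +
    corner(0,   0,   up3) * (1 - W1) * (1 - W2) * W3 +
    corner(up1, 0,   up3) * W1       * (1 - W2) * W3 +
    corner(0,   up2, up3) * (1 - W1) * W2       * W3 +
    corner(up1, up2, up3) * W1       * W2       * W3
  stopifnot(length(out) == n)
  doseGrid(array(out, sh), targetGrid)
}
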