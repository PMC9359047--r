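# shared fixtures: everything built in code, no files on disk

# random binary mask of given density
randomMask <- function(shape, density = 0.3, spacing = 2) {
  g <- makeGrid(shape, spacing)
  binaryMask(array(stats::runif(prod(shape)) < density, shape), g)
}

# axis-aligned block mask: voxel index ranges (1-based, inclusive)
blockMask <- function(grid, xr, yr, zr) {
  v <- array(FALSE, gridShape(grid))
  v[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  binaryMask(v, grid)
}

# independent scalar-loop even-odd point-in-polygon oracle (ray casting,
# one point at a time — deliberately unlike the vectorized implementation)
pipOracle <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xcross <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# count voxels of one slice whose centers fall inside a polygon, by the oracle
rasterOracleCount <- function(grid, vx, vy) {
  cx <- origin(grid)[1] + (seq_len(gridShape(grid)[1]) - 1) * spacing(grid)[1]
  cy <- origin(grid)[2] + (seq_len(gridShape(grid)[2]) - 1) * spacing(grid)[2]
  n <- 0L
  for (x in cx) for (y in cy) if (pipOracle(x, y, vx, vy)) n <- n + 1L
  n
}

# manual overlap count of fixed vs moving-translated-by-t, by direct array
# shifting in test code (third route, independent of the package)
overlapAt <- function(fixed, moving, t) {
  sh <- gridShape(fixed)
  f <- maskValues(fixed); m <- maskValues(moving)
  dstLo <- pmax(1, 1 + t); dstHi <- pmin(sh, sh + t)
  if (any(dstLo > dstHi)) return(0L)
  srcLo <- dstLo - t; srcHi <- dstHi - t
  sum(f[dstLo[1]:dstHi[1], dstLo[2]:dstHi[2], dstLo[3]:dstHi[3]] &
      m[srcLo[1]:srcHi[1], srcLo[2]:srcHi[2], srcLo[3]:srcHi[3]])
}

# small phantom parameters that fit a 48 x 48 x 32 grid at 3 mm
tinyPhantomParams <- function(seed = 1L, ...) {
  defaults <- list(gridShape = c(48L, 48L, 32L), spacing = 3,
                   ptvSemiAxes = c(25, 18, 25), bladderRadius = 16,
                   rectumRadius = 8, rectumLength = 60,
                   femoralHeadRadius = 12, femoralHeadLateralOffset = 45,
                   cordRadius = 4, cordPosteriorOffset = 40,
                   positionJitter = 3, seed = seed)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(phantomParams, defaults)
}

# a tiny synthetic patient record with handcrafted block anatomy; everything
# interior so rigid shifts stay on-grid
blockPatient <- function(id, grid, ptvShift = c(0, 0, 0),
                         bladderShift = c(0, 0, 0),
                         rectumShift = c(0, 0, 0),
                         achieved = NULL) {
  mk <- function(xr, yr, zr, s)
    blockMask(grid, xr + s[1], yr + s[2], zr + s[3])
  st <- structureSet(id, list(
    PTV = mk(c(10, 15), c(10, 15), c(8, 13), ptvShift),
    bladder = mk(c(10, 13), c(5, 8), c(8, 11), bladderShift),
    rectum = mk(c(11, 14), c(17, 19), c(6, 15), rectumShift)))
  if (is.null(achieved))
    achieved <- data.frame(structure = character(), metric = character(),
                           value = numeric())
  patientRecord(st, achievedDVH = achieved, provenance = "synthetic")
}

achievedRow <- function(structure, value)
  data.frame(structure = structure, metric = "V50Gy", value = value,
             stringsAsFactors = FALSE)
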