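#' @include similarity.R dvh.R
NULL

#' Default synthetic pelvic phantom parameters
#'
#' A desk-scale stand-in for a cervical-cancer planning cohort: an
#' ellipsoidal PTV centered in the pelvis, a spheroidal bladder
#' anterior-superior to it, a tubular rectum posterior to it (both with a
#' controllable penetration into the PTV), lateral femoral-head spheres and
#' a posterior midline spinal cord. Per-patient variation comes from
#' log-normal-free multiplicative size jitter and Gaussian center jitter.
#'
#' @param gridShape integer(3) voxels (default 96 x 96 x 64).
#' @param spacing isotropic voxel spacing, mm (default 2.5).
#' @param ptvSemiAxes PTV ellipsoid semi-axes, mm.
#' @param ptvCenter PTV center, mm.
#' @param bladderRadius,bladderPenetration,bladderSuperiorOffset mm.
#' @param rectumRadius,rectumLength,rectumPenetration mm.
#' @param femoralHeadRadius,femoralHeadLateralOffset mm.
#' @param cordRadius,cordPosteriorOffset mm.
#' @param sizeJitter fractional s.d. of size scaling (default 0.10).
#' @param positionJitter s.d. of center displacement, mm (default 5).
#' @param seed integer RNG seed.
#' @return a [PhantomParams].
#' @export
phantomParams <- function(gridShape = c(96L, 96L, 64L), spacing = 2.5,
                          ptvSemiAxes = c(45, 32, 45), ptvCenter = c(0, 0, 0),
                          bladderRadius = 30, bladderPenetration = 12,
                          bladderSuperiorOffset = 10,
                          rectumRadius = 14, rectumLength = 100,
                          rectumPenetration = 10,
                          femoralHeadRadius = 22,
                          femoralHeadLateralOffset = 80,
                          cordRadius = 6, cordPosteriorOffset = 78,
                          sizeJitter = 0.10, positionJitter = 5,
                          seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomParams", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), ptvSemiAxes = ptvSemiAxes,
      ptvCenter = ptvCenter, bladderRadius = bladderRadius,
      bladderPenetration = bladderPenetration,
      bladderSuperiorOffset = bladderSuperiorOffset,
      rectumRadius = rectumRadius, rectumLength = rectumLength,
      rectumPenetration = rectumPenetration,
      femoralHeadRadius = femoralHeadRadius,
      femoralHeadLateralOffset = femoralHeadLateralOffset,
      cordRadius = cordRadius, cordPosteriorOffset = cordPosteriorOffset,
      sizeJitter = sizeJitter, positionJitter = positionJitter,
      seed = as.integer(seed))
}

#' Dose-falloff model parameters
#'
#' @param prescription prescription dose, Gy (default 50).
#' @param sigma falloff scale, mm (default 3; the 80-20 penumbra width of
#'   the logistic profile is about `2.8 * sigma`).
#' @param hotspot maximum-dose multiplier (> 1; default 1.04, i.e. a 52 Gy
#'   hotspot for a 50 Gy prescription).
#' @param margin mm the prescription isodose surface sits outside the PTV
#'   surface (default 1).
#' @param noise s.d. of additive Gaussian dose noise, Gy (default 0:
#'   the surrogate is deterministic unless noise is requested).
#' @param seed integer RNG seed for the noise.
#' @return a [DoseModelParams].
#' @export
doseModelParams <- function(prescription = 50, sigma = 3, hotspot = 1.04,
                            margin = 1, noise = 0, seed = 1L)
  new("DoseModelParams", prescription = prescription, sigma = sigma,
      hotspot = hotspot, margin = margin, noise = noise,
      seed = as.integer(seed))

# voxel-center coordinate arrays of a grid (memory: 3 arrays of prod(shape))
.coordArrays <- function(grid) {
  sh <- grid@shape
  list(x = array(rep(.axisCenters(grid, 1L), times = sh[2L] * sh[3L]), sh),
       y = array(rep(rep(.axisCenters(grid, 2L), each = sh[1L]),
                     times = sh[3L]), sh),
       z = array(rep(.axisCenters(grid, 3L), each = sh[1L] * sh[2L]), sh))
}

.ellipsoid <- function(co, center, semi)
  ((co$x - center[1L]) / semi[1L])^2 + ((co$y - center[2L]) / semi[2L])^2 +
  ((co$z - center[3L]) / semi[3L])^2 <= 1

.sphere <- function(co, center, r)
  .ellipsoid(co, center, rep(r, 3L))

# tube along z
.tube <- function(co, center, r, length)
  ((co$x - center[1L])^2 + (co$y - center[2L])^2 <= r^2) &
  (abs(co$z - center[3L]) <= length / 2)

.checkInGrid <- function(grid, name, center, extent) {
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@shape - 0.5) * grid@spacing
  if (any(center - extent < lo) || any(center + extent > hi))
    stop("structure '", name, "' exceeds the grid extent")
}

# deterministic per-structure jitter draws for one phantom; draws are
# truncated at 2.5 s.d. (and sizes to [0.75, 1.25]x) so a jittered organ
# cannot escape the default grid extent
.jitter <- function(p) {
  clamp <- function(x, a) pmin(pmax(x, -a), a)
  scale <- function()
    min(1.25, max(0.75, 1 + clamp(stats::rnorm(1L, 0, p@sizeJitter),
                                  2.5 * p@sizeJitter)))
  shift <- function(n = 3L)
    clamp(stats::rnorm(n, 0, p@positionJitter), 2.5 * p@positionJitter)
  list(ptvScale = scale(), ptvShift = shift(),
       bladScale = scale(), bladShift = shift(),
       rectScale = scale(), rectShift = shift(),
       fhScale = scale(), fhShiftL = shift(), fhShiftR = shift(),
       cordShift = shift(2L))
}

#' Generate one synthetic pelvic phantom
#'
#' Deterministic for a given `params@seed`. With zero jitter the phantom is
#' left-right symmetric. Penetration parameters of 0 or less guarantee zero
#' overlap between that organ and the PTV.
#'
#' @param params a [PhantomParams].
#' @param patientID identifier for the resulting [StructureSet].
#' @return a [StructureSet] with PTV, rectum, bladder, both femoral heads
#'   and spinal cord on the common grid.
#' @export
makePhantom <- function(params, patientID = "PHANTOM") {
  grid <- makeGrid(params@gridShape, params@spacing)
  set.seed(params@seed)
  j <- if (params@sizeJitter > 0 || params@positionJitter > 0) .jitter(params)
       else list(ptvScale = 1, ptvShift = c(0, 0, 0), bladScale = 1,
                 bladShift = c(0, 0, 0), rectScale = 1, rectShift = c(0, 0, 0),
                 fhScale = 1, fhShiftL = c(0, 0, 0), fhShiftR = c(0, 0, 0),
                 cordShift = c(0, 0))
  co <- .coordArrays(grid)

  semi <- params@ptvSemiAxes * j$ptvScale
  ptvC <- params@ptvCenter + j$ptvShift
  .checkInGrid(grid, "PTV", ptvC, semi)
  ptv <- .ellipsoid(co, ptvC, semi)

  # bladder: anterior (-y); its surface reaches `penetration` mm past the
  # PTV surface along -y from the PTV center
  bR <- params@bladderRadius * j$bladScale
  bC <- c(ptvC[1L] + j$bladShift[1L],
          ptvC[2L] - (semi[2L] + bR - params@bladderPenetration) +
            j$bladShift[2L],
          ptvC[3L] + params@bladderSuperiorOffset + j$bladShift[3L])
  .checkInGrid(grid, "bladder", bC, rep(bR, 3L))
  bladder <- .sphere(co, bC, bR)

  # rectum: posterior (+y) tube along z
  rR <- params@rectumRadius * j$rectScale
  rL <- params@rectumLength * j$rectScale
  rC <- c(ptvC[1L] + j$rectShift[1L],
          ptvC[2L] + (semi[2L] + rR - params@rectumPenetration) +
            j$rectShift[2L],
          ptvC[3L] + j$rectShift[3L])
  .checkInGrid(grid, "rectum", rC, c(rR, rR, rL / 2))
  rectum <- .tube(co, rC, rR, rL)

  fR <- params@femoralHeadRadius * j$fhScale
  fLc <- c(params@femoralHeadLateralOffset, 0, 0) + j$fhShiftL
  fRc <- c(-params@femoralHeadLateralOffset, 0, 0) + j$fhShiftR
  .checkInGrid(grid, "femoral_head_L", fLc, rep(fR, 3L))
  .checkInGrid(grid, "femoral_head_R", fRc, rep(fR, 3L))
  fhL <- .sphere(co, fLc, fR)
  fhR <- .sphere(co, fRc, fR)

  cordC <- c(j$cordShift[1L], params@cordPosteriorOffset + j$cordShift[2L], 0)
  cordL <- (grid@shape[3L] - 1L) * grid@spacing[3L]
  .checkInGrid(grid, "spinal_cord", cordC,
               c(params@cordRadius, params@cordRadius, cordL / 2))
  cord <- .tube(co, cordC, params@cordRadius, cordL)

  structureSet(patientID, list(
    PTV = binaryMask(ptv, grid),
    rectum = binaryMask(rectum, grid),
    bladder = binaryMask(bladder, grid),
    femoral_head_L = binaryMask(fhL, grid),
    femoral_head_R = binaryMask(fhR, grid),
    spinal_cord = binaryMask(cord, grid)))
}

#' Signed Euclidean distance from a mask surface
#'
#' Positive outside the mask, negative inside; computed between voxel
#' centers of opposite phase with an exact anisotropic distance transform,
#' so the zero level sits between the boundary voxel layers (a boundary
#' voxel has |s| of about one spacing, never exactly 0).
#'
#' @param mask a [BinaryMask] that is neither empty nor full.
#' @return numeric 3D array of distances in mm.
#' @export
signedDistance <- function(mask) {
  v <- mask@values
  n1 <- sum(v)
  if (n1 == 0L || n1 == length(v))
    stop("signed distance needs both inside and outside voxels")
  sh <- mask@grid@shape; sp <- mask@grid@spacing
  dOut <- sqrt(cpp_edt_sq(as.logical(v), sh, sp))    # 0 inside mask
  dIn <- sqrt(cpp_edt_sq(!as.logical(v), sh, sp))    # 0 outside mask
  array(dOut - dIn, sh)
}

#' The logistic dose-falloff profile
#'
#' `D(s) = hotspot * prescription / (1 + exp((s - mu) / sigma))` with
#' `mu = margin - sigma * log(hotspot - 1)`, so `D(margin) = prescription`
#' exactly: the prescription isodose sits `margin` mm outside the PTV
#' surface, the profile midpoint (`hotspot * prescription / 2`) at `s = mu`,
#' and the dose deep inside the PTV approaches `hotspot * prescription`.
#'
#' @param s signed distance(s) from the PTV surface, mm.
#' @param params a [DoseModelParams].
#' @return dose in Gy, same shape as `s`.
#' @export
doseProfile <- function(s, params) {
  mu <- params@margin - params@sigma * log(params@hotspot - 1)
  params@hotspot * params@prescription / (1 + exp((s - mu) / params@sigma))
}

#' Synthesize an achievable dose distribution for a phantom
#'
#' A deterministic surrogate for inverse-optimized planning: the dose is the
#' logistic profile [doseProfile()] of the signed Euclidean distance from
#' the PTV surface, plus optional Gaussian noise (clamped at 0 Gy). It makes
#' the achievable dose a smooth function of anatomy, which is the premise of
#' knowledge-based constraint transfer.
#'
#' @param structures a [StructureSet] with a PTV.
#' @param params a [DoseModelParams].
#' @return a [DoseGrid] on the structures' grid.
#' @export
synthDose <- function(structures, params = doseModelParams()) {
  ptv <- getStructure(structures, "PTV")
  s <- signedDistance(ptv)
  d <- doseProfile(s, params)
  if (params@noise > 0) {
    set.seed(params@seed)
    d <- d + stats::rnorm(length(d), 0, params@noise)
    d[d < 0] <- 0
  }
  doseGrid(array(d, dim(s)), ptv@grid)
}

# achieved DVH table of a synthetic plan (V50Gy for the OARs and PTV)
.achievedTable <- function(structures, dose, prescription, binWidth = 0.05) {
  rows <- list()
  for (nm in intersect(structureNames(structures),
                       c("PTV", "rectum", "bladder", "femoral_head_L",
                         "femoral_head_R", "small_intestine"))) {
    m <- getStructure(structures, nm)
    if (sum(m@values) == 0L) next
    cv <- cumulativeDVH(dose, m, binWidth, structure = nm)
    rows[[length(rows) + 1L]] <- data.frame(
      structure = nm, metric = "V50Gy",
      value = vAtDose(cv, prescription), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic patient database
#'
#' `n` independently jittered phantoms with achieved dose-volume parameters
#' computed from the synthetic dose model through the package's own DVH
#' code. Deterministic for a given `seed`; per-patient seeds are derived
#' from it.
#'
#' @param n number of patients.
#' @param base a [PhantomParams] giving the population means and jitter
#'   scales.
#' @param doseParams a [DoseModelParams].
#' @param seed integer master seed.
#' @param idPrefix patient IDs are `sprintf("%s%03d", idPrefix, i)`.
#' @return list of `n` [PatientRecord] objects with `provenance`
#'   `"synthetic"` and rectum/bladder (and PTV) V50Gy filled in.
#' @export
makeDatabase <- function(n, base = phantomParams(),
                         doseParams = doseModelParams(), seed = 1L,
                         idPrefix = "SYN") {
  stopifnot(n >= 1)
  set.seed(seed)
  seeds <- sample.int(2^31 - 1L, 2L * n)
  lapply(seq_len(n), function(i) {
    p <- base
    p@seed <- seeds[2L * i - 1L]
    st <- makePhantom(p, patientID = sprintf("%s%03d", idPrefix, i))
    dp <- doseParams
    dp@seed <- seeds[2L * i]
    dose <- synthDose(st, dp)
    patientRecord(st,
                  achievedDVH = .achievedTable(st, dose,
                                               doseParams@prescription),
                  provenance = "synthetic")
  })
}
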