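#' @import methods
NULL

# canonical structure vocabulary shared by the whole package
.CANONICAL_STRUCTURES <- c("PTV", "rectum", "bladder", "femoral_head_L",
                           "femoral_head_R", "small_intestine", "spinal_cord")

#' VoxelGrid: geometry of a regular 3D voxel lattice
#'
#' A `VoxelGrid` describes an axis-aligned voxel lattice in patient
#' coordinates (mm, DICOM LPS convention): the number of voxels per axis,
#' the voxel spacing, and the position of the center of voxel `(0,0,0)`.
#' Voxel indices are 0-based in the coordinate algebra; the center of voxel
#' `(i,j,k)` lies at `origin + c(i,j,k) * spacing`.
#'
#' @slot shape integer(3), voxels per axis, all >= 1.
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), mm position of the center of voxel (0,0,0).
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(is.na(object@shape)) ||
        any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 integers, all >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: 3D binary occupancy of one structure
#'
#' Binary intensities on a [VoxelGrid]: `TRUE` (1) inside the structure,
#' `FALSE` (0) outside.
#'
#' @slot grid a [VoxelGrid].
#' @slot values logical 3D array of dimension `shape(grid)`.
#' @export
setClass("BinaryMask",
  representation(grid = "VoxelGrid", values = "array"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@values))
      msg <- c(msg, "values must be a logical array")
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      msg <- c(msg, "dim(values) must equal the grid shape")
    if (anyNA(object@values))
      msg <- c(msg, "values must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' StructureSet: named structure masks of one patient on a shared grid
#'
#' @slot patientID character scalar.
#' @slot structures named list of [BinaryMask] objects, all on one grid;
#'   names drawn from the canonical vocabulary
#'   (PTV, rectum, bladder, femoral_head_L, femoral_head_R,
#'   small_intestine, spinal_cord); PTV must be present.
#' @export
setClass("StructureSet",
  representation(patientID = "character", structures = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@patientID) != 1L || is.na(object@patientID))
      msg <- c(msg, "patientID must be a single string")
    st <- object@structures
    if (is.null(names(st)) || any(!nzchar(names(st))))
      msg <- c(msg, "structures must be a named list")
    bad <- setdiff(names(st), .CANONICAL_STRUCTURES)
    if (length(bad))
      msg <- c(msg, paste0("non-canonical structure name(s): ",
                           paste(bad, collapse = ", ")))
    if (!"PTV" %in% names(st))
      msg <- c(msg, "PTV structure is required")
    if (!all(vapply(st, is, logical(1), class2 = "BinaryMask")))
      msg <- c(msg, "all structures must be BinaryMask objects")
    if (length(st) > 1L) {
      g0 <- st[[1L]]@grid
      same <- vapply(st, function(m) sameGrid(m@grid, g0), logical(1))
      if (!all(same))
        msg <- c(msg, "all structures must share one voxel grid")
    }
    if (length(msg)) msg else TRUE
  })

#' DoseGrid: absorbed dose (Gy) on a voxel grid
#'
#' @slot grid a [VoxelGrid].
#' @slot dose numeric 3D array of dose in Gy; finite and >= 0.
#' @export
setClass("DoseGrid",
  representation(grid = "VoxelGrid", dose = "array"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@dose))
      msg <- c(msg, "dose must be a numeric array")
    if (!identical(dim(object@dose), as.integer(object@grid@shape)))
      msg <- c(msg, "dim(dose) must equal the grid shape")
    if (any(!is.finite(object@dose)) || any(object@dose < 0))
      msg <- c(msg, "dose must be finite and non-negative (Gy)")
    if (length(msg)) msg else TRUE
  })

#' ScoreVolume: spatial correlation over all candidate translations
#'
#' `scores[iu, iv, iw]` is the integer overlap voxel count between the fixed
#' mask and the moving mask translated by
#' `(uOffsets[iu], vOffsets[iv], wOffsets[iw])` voxels. The offsets cover the
#' full linear-correlation range `-(Nm-1) .. (Nf-1)` along each axis, where
#' `Nf`/`Nm` are the fixed/moving grid shapes.
#'
#' @slot scores numeric 3D array of overlap counts (integers after rounding).
#' @slot uOffsets,vOffsets,wOffsets integer vectors mapping array indices to
#'   signed voxel translations.
#' @slot spacing numeric(3) voxel spacing (mm), used for mm tie-breaks.
#' @export
setClass("ScoreVolume",
  representation(scores = "array", uOffsets = "integer", vOffsets = "integer",
                 wOffsets = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@scores)
    if (length(d) != 3L)
      msg <- c(msg, "scores must be a 3D array")
    if (!identical(d, c(length(object@uOffsets), length(object@vOffsets),
                        length(object@wOffsets))))
      msg <- c(msg, "offset vectors must match dim(scores)")
    if (any(object@scores < 0))
      msg <- c(msg, "scores must be non-negative overlap counts")
    if (length(msg)) msg else TRUE
  })

#' RegistrationResult: the optimal translation and its overlap score
#'
#' @slot translation integer(3) voxel offsets (u, v, w) to apply to the
#'   moving mask.
#' @slot score numeric scalar, overlap voxel count at the optimum.
#' @export
setClass("RegistrationResult",
  representation(translation = "integer", score = "numeric"),
  validity = function(object) {
    if (length(object@translation) != 3L || anyNA(object@translation))
      return("translation must be 3 integers")
    if (length(object@score) != 1L || object@score < 0)
      return("score must be a non-negative scalar")
    TRUE
  })

#' SimilarityRecord: DSC scores of one database patient against a test patient
#'
#' @slot patientID database patient identifier.
#' @slot translation integer(3), the PTV-registration translation applied to
#'   the candidate's structures.
#' @slot dsc named numeric vector of Dice coefficients (PTV, rectum, bladder),
#'   each in `[0, 1]`.
#' @export
setClass("SimilarityRecord",
  representation(patientID = "character", translation = "integer",
                 dsc = "numeric"),
  validity = function(object) {
    if (any(object@dsc < 0 | object@dsc > 1, na.rm = TRUE))
      return("all DSC values must lie in [0, 1]")
    if (length(object@translation) != 3L)
      return("translation must be 3 integers")
    TRUE
  })

#' PatientRecord: structures plus achieved dose-volume parameters of one plan
#'
#' @slot structures a [StructureSet].
#' @slot achievedDVH data.frame with columns `structure`, `metric`, `value`;
#'   VxGy values are percent in `[0, 100]`, Dx values are Gy >= 0.
#' @slot provenance `"clinical"` or `"synthetic"`.
#' @export
setClass("PatientRecord",
  representation(structures = "StructureSet", achievedDVH = "data.frame",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    df <- object@achievedDVH
    need <- c("structure", "metric", "value")
    if (!all(need %in% names(df)))
      msg <- c(msg, "achievedDVH needs columns structure, metric, value")
    else {
      vx <- grepl("^V[0-9.]+Gy$", df$metric)
      if (any(df$value[vx] < 0 | df$value[vx] > 100, na.rm = TRUE))
        msg <- c(msg, "VxGy values must lie in [0, 100] percent")
      if (any(df$value[!vx] < 0, na.rm = TRUE))
        msg <- c(msg, "dose metrics must be >= 0 Gy")
    }
    if (!object@provenance %in% c("clinical", "synthetic"))
      msg <- c(msg, "provenance must be 'clinical' or 'synthetic'")
    if (length(msg)) msg else TRUE
  })

#' MatchSelection: two-stage similar-patient selection and derived constraints
#'
#' @slot scoreTable data.frame of all scored database patients (columns
#'   `patient_id`, `dsc_ptv`, `dsc_rectum`, `dsc_bladder`, `tu`, `tv`, `tw`).
#' @slot ptvTop character vector of patient IDs, the top-`k_ptv` PTV matches
#'   in descending PTV-DSC order.
#' @slot rectumTop,bladderTop character vectors of the top-`k_oar` IDs per
#'   organ, subsets of `ptvTop`.
#' @slot constraints named numeric: derived V50Gy constraint (percent) for
#'   `rectum` and `bladder` (minimum achieved value over the matched
#'   patients); `NA` when achieved values were unavailable.
#' @export
setClass("MatchSelection",
  representation(scoreTable = "data.frame", ptvTop = "character",
                 rectumTop = "character", bladderTop = "character",
                 constraints = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@rectumTop %in% object@ptvTop))
      msg <- c(msg, "rectumTop must be a subset of ptvTop")
    if (!all(object@bladderTop %in% object@ptvTop))
      msg <- c(msg, "bladderTop must be a subset of ptvTop")
    if (!all(c("rectum", "bladder") %in% names(object@constraints)))
      msg <- c(msg, "constraints must be named for rectum and bladder")
    if (length(msg)) msg else TRUE
  })

#' DVHCurve: cumulative dose-volume histogram of one structure
#'
#' `volumeFraction[i]` is the percent of the structure volume receiving at
#' least `doseEdges[i]` Gy. The raw per-voxel doses are retained (sorted) so
#' that `vAtDose()` can be exact rather than interpolated.
#'
#' @slot doseEdges numeric, ascending from 0 (Gy).
#' @slot volumeFraction numeric, percent, non-increasing, starts at 100.
#' @slot structure character, structure name.
#' @slot totalVolumeCc numeric, structure volume in cc.
#' @slot voxelDoses numeric, sorted per-voxel doses (Gy).
#' @export
setClass("DVHCurve",
  representation(doseEdges = "numeric", volumeFraction = "numeric",
                 structure = "character", totalVolumeCc = "numeric",
                 voxelDoses = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@doseEdges) != length(object@volumeFraction))
      msg <- c(msg, "doseEdges and volumeFraction lengths differ")
    if (length(object@doseEdges) && object@doseEdges[1L] != 0)
      msg <- c(msg, "doseEdges must start at 0 Gy")
    if (is.unsorted(object@doseEdges, strictly = TRUE))
      msg <- c(msg, "doseEdges must be strictly increasing")
    vf <- object@volumeFraction
    if (length(vf)) {
      if (abs(vf[1L] - 100) > 1e-9)
        msg <- c(msg, "volumeFraction must start at 100%")
      if (any(diff(vf) > 1e-9))
        msg <- c(msg, "volumeFraction must be non-increasing")
      if (any(vf < -1e-9 | vf > 100 + 1e-9))
        msg <- c(msg, "volumeFraction must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
  })

#' PhantomParams: geometry of the synthetic pelvic phantom
#'
#' All lengths are in mm; patient coordinates follow LPS (+x left,
#' +y posterior, +z superior), so the bladder sits at negative y (anterior)
#' and the rectum at positive y (posterior). `rectumPenetration` and
#' `bladderPenetration` set how far (mm) each organ's surface reaches past
#' the PTV surface along y; 0 or negative gives zero overlap.
#'
#' @slot gridShape integer(3) voxels; @slot spacing numeric(3) mm;
#' @slot ptvSemiAxes numeric(3) ellipsoid semi-axes; @slot ptvCenter numeric(3).
#' @slot bladderRadius,bladderPenetration,bladderSuperiorOffset numeric (mm).
#' @slot rectumRadius,rectumLength,rectumPenetration numeric (mm).
#' @slot femoralHeadRadius,femoralHeadLateralOffset numeric (mm).
#' @slot cordRadius,cordPosteriorOffset numeric (mm).
#' @slot sizeJitter fractional s.d. of per-patient size scaling;
#' @slot positionJitter s.d. (mm) of per-patient center displacement.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomParams",
  representation(gridShape = "integer", spacing = "numeric",
                 ptvSemiAxes = "numeric", ptvCenter = "numeric",
                 bladderRadius = "numeric", bladderPenetration = "numeric",
                 bladderSuperiorOffset = "numeric",
                 rectumRadius = "numeric", rectumLength = "numeric",
                 rectumPenetration = "numeric",
                 femoralHeadRadius = "numeric",
                 femoralHeadLateralOffset = "numeric",
                 cordRadius = "numeric", cordPosteriorOffset = "numeric",
                 sizeJitter = "numeric", positionJitter = "numeric",
                 seed = "integer"),
  validity = function(object) {
    lens <- c(object@ptvSemiAxes, object@bladderRadius, object@rectumRadius,
              object@rectumLength, object@femoralHeadRadius,
              object@cordRadius)
    if (any(!is.finite(lens)) || any(lens <= 0))
      return("all structure dimensions must be positive")
    if (any(object@gridShape < 8L))
      return("gridShape entries must be >= 8 voxels")
    if (object@sizeJitter < 0 || object@positionJitter < 0)
      return("jitter scales must be >= 0")
    TRUE
  })

#' DoseModelParams: parametric dose-falloff surrogate
#'
#' Dose is a logistic function of the signed Euclidean distance `s` (mm) from
#' the PTV surface (negative inside):
#' `D(s) = hotspot * prescription / (1 + exp((s - mu) / sigma))`, with
#' `mu = margin - sigma * log(hotspot - 1)` so the prescription isodose
#' surface sits exactly `margin` mm outside the PTV. Optional zero-mean
#' Gaussian noise (s.d. `noise` Gy) is added and the result clamped at 0.
#'
#' @slot prescription Gy (default 50); @slot sigma falloff scale mm (> 0);
#' @slot hotspot max-dose multiplier (> 1); @slot margin mm;
#' @slot noise Gy (>= 0); @slot seed integer RNG seed.
#' @export
setClass("DoseModelParams",
  representation(prescription = "numeric", sigma = "numeric",
                 hotspot = "numeric", margin = "numeric",
                 noise = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@prescription <= 0) msg <- c(msg, "prescription must be > 0")
    if (object@hotspot <= 1) msg <- c(msg, "hotspot must be > 1")
    if (object@noise < 0) msg <- c(msg, "noise must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PipelineConfig: end-to-end workflow configuration
#'
#' @slot gridShape integer(3); @slot spacing numeric(3) mm;
#' @slot origin numeric(3) mm (NA = center the grid on the patient origin).
#' @slot kPtv,kOar integers, two-stage selection sizes (kPtv >= kOar >= 1).
#' @slot binWidth DVH bin width, Gy.
#' @slot aliasTable named character vector mapping ROI aliases to canonical
#'   structure names.
#' @slot seed integer.
#' @export
setClass("PipelineConfig",
  representation(gridShape = "integer", spacing = "numeric",
                 origin = "numeric", kPtv = "integer", kOar = "integer",
                 binWidth = "numeric", aliasTable = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@kPtv < object@kOar || object@kOar < 1L)
      msg <- c(msg, "need kPtv >= kOar >= 1")
    if (any(object@spacing <= 0))
      msg <- c(msg, "spacing must be > 0")
    if (object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })
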