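#' @include AllGenerics.R
NULL

#' Construct a VoxelGrid
#'
#' @param shape integer(3), voxels per axis.
#' @param spacing numeric, voxel spacing in mm; a scalar is recycled to an
#'   isotropic triple.
#' @param origin numeric(3), mm position of the center of voxel (0,0,0);
#'   `NULL` centers the grid on (0,0,0).
#' @return a [VoxelGrid].
#' @examples
#' g <- makeGrid(c(64, 64, 48), 2.5)
#' gridShape(g)
#' @export
makeGrid <- function(shape, spacing = 2.5, origin = NULL) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  new("VoxelGrid", shape = shape, spacing = spacing,
      origin = as.numeric(origin))
}

#' Test whether two grids describe the same lattice
#' @param a,b [VoxelGrid] objects.
#' @param tol mm tolerance on spacing and origin.
#' @return logical scalar.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

# voxel-center coordinates along one axis, mm
.axisCenters <- function(grid, axis)
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]

#' Construct a BinaryMask from a logical array
#'
#' @param values logical (or 0/1) 3D array matching the grid shape.
#' @param grid a [VoxelGrid].
#' @return a [BinaryMask].
#' @export
binaryMask <- function(values, grid) {
  v <- array(as.logical(values), dim = dim(values))
  new("BinaryMask", grid = grid, values = v)
}

#' An all-empty mask on a grid
#' @param grid a [VoxelGrid].
#' @export
emptyMask <- function(grid)
  binaryMask(array(FALSE, grid@shape), grid)

#' Construct a StructureSet
#'
#' @param patientID character scalar.
#' @param structures named list of [BinaryMask] on a shared grid; must
#'   include `PTV`.
#' @return a [StructureSet].
#' @export
structureSet <- function(patientID, structures)
  new("StructureSet", patientID = as.character(patientID),
      structures = structures)

#' Construct a DoseGrid
#' @param dose numeric 3D array (Gy).
#' @param grid a [VoxelGrid].
#' @export
doseGrid <- function(dose, grid)
  new("DoseGrid", grid = grid, dose = array(as.numeric(dose), dim(dose)))

## ---- accessors -------------------------------------------------------------

#' @describeIn spacing spacing of a VoxelGrid
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)
#' @describeIn spacing spacing of a mask's grid
#' @export
setMethod("spacing", "BinaryMask", function(x) x@grid@spacing)
#' @describeIn spacing spacing of a dose grid
#' @export
setMethod("spacing", "DoseGrid", function(x) x@grid@spacing)

#' @describeIn origin origin of a VoxelGrid
#' @export
setMethod("origin", "VoxelGrid", function(x) x@origin)
#' @describeIn origin origin of a mask's grid
#' @export
setMethod("origin", "BinaryMask", function(x) x@grid@origin)

#' @describeIn gridShape shape of a VoxelGrid
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @describeIn gridShape shape of a mask's grid
#' @export
setMethod("gridShape", "BinaryMask", function(x) x@grid@shape)
#' @describeIn gridShape shape of a dose grid
#' @export
setMethod("gridShape", "DoseGrid", function(x) x@grid@shape)

#' @describeIn voxelGrid grid of a mask
#' @export
setMethod("voxelGrid", "BinaryMask", function(x) x@grid)
#' @describeIn voxelGrid grid of a dose grid
#' @export
setMethod("voxelGrid", "DoseGrid", function(x) x@grid)
#' @describeIn voxelGrid shared grid of a structure set
#' @export
setMethod("voxelGrid", "StructureSet",
          function(x) x@structures[[1L]]@grid)

#' @describeIn voxelCount occupied voxels of a mask
#' @export
setMethod("voxelCount", "BinaryMask", function(x) sum(x@values))

#' @describeIn structureVolume physical volume (cc) of a mask
#' @export
setMethod("structureVolume", "BinaryMask",
          function(x) sum(x@values) * prod(x@grid@spacing) / 1000)

#' Mask values as a logical array
#' @param mask a [BinaryMask].
#' @export
maskValues <- function(mask) mask@values

#' Dose values as a numeric array (Gy)
#' @param dose a [DoseGrid].
#' @export
doseValues <- function(dose) dose@dose

#' @describeIn structureNames names within a StructureSet
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@structures))

#' @describeIn getStructure extract a mask from a StructureSet
#' @export
setMethod("getStructure", "StructureSet", function(x, name) {
  if (!name %in% names(x@structures))
    stop("structure '", name, "' not present for patient ", x@patientID)
  x@structures[[name]]
})

#' @describeIn patientID patient ID of a StructureSet
#' @export
setMethod("patientID", "StructureSet", function(x) x@patientID)

## ---- show methods ----------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d / %d voxels set (%.2f cc)\n",
              sum(object@values), length(object@values),
              structureVolume(object)))
  show(object@grid)
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet for patient '%s': %d structure(s)\n",
              object@patientID, length(object@structures)))
  for (nm in names(object@structures))
    cat(sprintf("  %-16s %8d voxels (%.1f cc)\n", nm,
                sum(object@structures[[nm]]@values),
                structureVolume(object@structures[[nm]])))
})

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid: max %.2f Gy, mean %.2f Gy\n",
              max(object@dose), mean(object@dose)))
  show(object@grid)
})
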