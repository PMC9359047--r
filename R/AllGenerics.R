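#' @include AllClasses.R
NULL

#' Voxel spacing of an object's grid (mm)
#' @param x an object with a voxel grid.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Grid origin (mm position of the center of voxel (0,0,0))
#' @param x an object with a voxel grid.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Grid shape (voxels per axis)
#' @param x an object with a voxel grid.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' The underlying VoxelGrid of an object
#' @param x an object with a voxel grid.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Number of occupied (1) voxels of a mask
#' @param x a [BinaryMask].
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Physical volume in cc
#' @param x a [BinaryMask].
#' @export
setGeneric("structureVolume", function(x) standardGeneric("structureVolume"))

#' Names of the structures present
#' @param x a [StructureSet] or [PatientRecord].
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Extract one structure mask
#' @param x a [StructureSet] or [PatientRecord].
#' @param name canonical structure name.
#' @export
setGeneric("getStructure", function(x, name) standardGeneric("getStructure"))

#' Patient identifier
#' @param x a [StructureSet] or [PatientRecord].
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))

#' Achieved dose-volume parameters of a patient's plan
#' @param x a [PatientRecord].
#' @export
setGeneric("achievedDVH", function(x) standardGeneric("achievedDVH"))

#' Derived dose constraints of a match selection
#' @param x a [MatchSelection].
#' @export
setGeneric("constraints", function(x) standardGeneric("constraints"))

#' Full similarity score table of a match selection
#' @param x a [MatchSelection].
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' Optimal translation of a registration result (voxels)
#' @param x a [RegistrationResult] or [SimilarityRecord].
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' Overlap score at the registration optimum
#' @param x a [RegistrationResult].
#' @export
setGeneric("regScore", function(x) standardGeneric("regScore"))
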