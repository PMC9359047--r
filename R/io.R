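#' @include contours.R resample.R similarity.R
NULL

#' Default structure-name alias table
#'
#' Clinical ROI naming is inconsistent; structures are matched to the
#' canonical vocabulary through this user-extendable table. Matching is
#' case-insensitive after collapsing runs of non-alphanumeric characters to
#' a single underscore, so `"Bladder_full"`, `"bladder full"` and
#' `"BLADDER-FULL"` all hit the same alias.
#'
#' @return named character vector: names are normalized aliases, values are
#'   canonical structure names.
#' @export
defaultStructureAliases <- function() {
  c(ptv = "PTV", ptv50 = "PTV", ptv_50 = "PTV", target = "PTV",
    rectum = "rectum",
    bladder = "bladder", bladder_full = "bladder",
    femoral_head_l = "femoral_head_L", left_femoral_head = "femoral_head_L",
    femhead_l = "femoral_head_L", femoral_head_left = "femoral_head_L",
    femoral_head_r = "femoral_head_R", right_femoral_head = "femoral_head_R",
    femhead_r = "femoral_head_R", femoral_head_right = "femoral_head_R",
    small_intestine = "small_intestine", bowel = "small_intestine",
    small_bowel = "small_intestine",
    spinal_cord = "spinal_cord", cord = "spinal_cord",
    sc = "spinal_cord")
}

.normalizeROIName <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

# map raw ROI names to canonical names; NA where no alias matches
.canonicalNames <- function(raw, aliasTable) {
  norm <- .normalizeROIName(raw)
  hit <- unname(aliasTable[norm])
  # a raw name that IS already canonical (any case) also matches
  direct <- match(norm, .normalizeROIName(.CANONICAL_STRUCTURES))
  hit[is.na(hit) & !is.na(direct)] <-
    .CANONICAL_STRUCTURES[direct[is.na(hit) & !is.na(direct)]]
  hit
}

#' Read a structure set from a contour file
#'
#' Reads a plain-text (JSON) contour file — the package's stand-in for a
#' DICOM RTSTRUCT — and rasterizes every recognized ROI onto `targetGrid`.
#' The file holds a `patient_id` and a list of `rois`, each with a `name`
#' and `contours` (per contour: `z` plane in mm plus `x`/`y` polygon vertex
#' arrays in mm). ROIs whose name does not map to the canonical vocabulary
#' through the alias table are ignored with a warning; a file without a PTV
#' is an error.
#'
#' @param path contour JSON file.
#' @param targetGrid [VoxelGrid] to rasterize onto.
#' @param aliasTable alias mapping, see [defaultStructureAliases()].
#' @return a [StructureSet].
#' @export
readContourSet <- function(path, targetGrid,
                           aliasTable = defaultStructureAliases()) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("malformed contour file '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$patient_id) || is.null(doc$rois))
    stop("malformed contour file '", path,
         "': needs fields patient_id and rois")
  raw <- vapply(doc$rois, function(r) as.character(r$name), character(1))
  canon <- .canonicalNames(raw, aliasTable)
  if (any(is.na(canon)))
    warning("ignoring unrecognized ROI(s) in '", path, "': ",
            paste(raw[is.na(canon)], collapse = ", "))
  structures <- list()
  for (i in seq_along(doc$rois)) {
    if (is.na(canon[i])) next
    contours <- lapply(doc$rois[[i]]$contours, function(ct)
      list(z = as.numeric(ct$z), x = as.numeric(unlist(ct$x)),
           y = as.numeric(unlist(ct$y))))
    structures[[canon[i]]] <- rasterizePolygonStack(contours, targetGrid)
  }
  if (!"PTV" %in% names(structures))
    stop("contour file '", path, "' contains no ROI mapping to PTV")
  structureSet(as.character(doc$patient_id), structures)
}

#' Read a dose grid from a dose file
#'
#' Reads the package's plain-text (JSON) dose format — the stand-in for a
#' DICOM RTDOSE: `shape`, `spacing`, `origin`, a mandatory `scaling` factor
#' and the flattened (column-major) stored `values`; dose in Gy is
#' `values * scaling`. When `targetGrid` is given the dose is resampled
#' onto it by trilinear interpolation.
#'
#' @param path dose JSON file.
#' @param targetGrid optional [VoxelGrid] to resample onto.
#' @return a [DoseGrid].
#' @export
readDoseGrid <- function(path, targetGrid = NULL) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed dose file '", path, "': ",
                         conditionMessage(e)))
  for (f in c("shape", "spacing", "origin", "values"))
    if (is.null(doc[[f]]))
      stop("malformed dose file '", path, "': missing field '", f, "'")
  if (is.null(doc$scaling))
    stop("dose file '", path, "' lacks the dose grid scaling attribute")
  grid <- makeGrid(doc$shape, doc$spacing, doc$origin)
  dg <- doseGrid(array(as.numeric(doc$values) * as.numeric(doc$scaling),
                       grid@shape), grid)
  if (!is.null(targetGrid)) dg <- resampleDose(dg, targetGrid)
  dg
}

#' Write a dose grid to the plain-text dose format
#' @param dose a [DoseGrid].
#' @param path output file.
#' @param scaling stored-value scaling factor (values written are
#'   `dose / scaling`).
#' @export
writeDoseGrid <- function(dose, path, scaling = 1e-4) {
  doc <- list(shape = dose@grid@shape, spacing = dose@grid@spacing,
              origin = dose@grid@origin, scaling = scaling,
              values = as.vector(round(dose@dose / scaling)))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# run-length encoding of a logical vector: run lengths of alternating
# values starting with FALSE (a leading TRUE run gets a 0 first entry)
.rleEncode <- function(v) {
  r <- rle(as.logical(v))
  if (r$values[1L]) c(0L, r$lengths) else r$lengths
}

.rleDecode <- function(lengths, n) {
  lengths <- as.integer(lengths)
  vals <- rep(c(FALSE, TRUE), length.out = length(lengths))
  out <- rep(vals, lengths)
  if (length(out) != n)
    stop("corrupt run-length data: expected ", n, " voxels, got ",
         length(out))
  out
}

#' Write a patient record as a mask bundle
#'
#' One JSON file per patient — the package's plain-text stand-in for
#' per-structure NIfTI masks plus a sidecar: patient ID, grid metadata,
#' run-length-encoded occupancy per structure, achieved DVH parameters and
#' provenance.
#'
#' @param record a [PatientRecord].
#' @param path output file.
#' @export
writePatientRecord <- function(record, path) {
  st <- record@structures
  grid <- voxelGrid(st)
  doc <- list(
    patient_id = patientID(record),
    grid = list(shape = grid@shape, spacing = grid@spacing,
                origin = grid@origin),
    provenance = record@provenance,
    structures = lapply(st@structures, function(m)
      .rleEncode(as.vector(m@values))),
    achieved_dvh = record@achievedDVH)
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a patient record from a mask bundle
#' @param path mask-bundle JSON file written by [writePatientRecord()].
#' @return a [PatientRecord].
#' @export
readPatientRecord <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed mask bundle '", path, "': ",
                         conditionMessage(e)))
  grid <- makeGrid(doc$grid$shape, doc$grid$spacing, doc$grid$origin)
  n <- prod(grid@shape)
  masks <- lapply(doc$structures, function(lens)
    binaryMask(array(.rleDecode(lens, n), grid@shape), grid))
  raw <- doc$achieved_dvh
  hasRows <- is.list(raw) &&
    all(c("structure", "metric", "value") %in% names(raw)) &&
    length(unlist(raw$structure)) > 0L
  adf <- if (hasRows)
    data.frame(structure = as.character(unlist(raw$structure)),
               metric = as.character(unlist(raw$metric)),
               value = as.numeric(unlist(raw$value)),
               stringsAsFactors = FALSE)
  else
    data.frame(structure = character(), metric = character(),
               value = numeric())
  patientRecord(structureSet(as.character(doc$patient_id), masks),
                achievedDVH = adf,
                provenance = as.character(doc$provenance))
}
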