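#' @include registration.R
NULL

#' Construct a PatientRecord
#'
#' @param structures a [StructureSet].
#' @param achievedDVH data.frame with columns `structure`, `metric`, `value`
#'   holding the dose-volume parameters achieved by the patient's plan
#'   (e.g. rectum V50Gy in percent); may be empty for contour-only records.
#' @param provenance `"clinical"` or `"synthetic"`.
#' @return a [PatientRecord].
#' @export
patientRecord <- function(structures,
                          achievedDVH = data.frame(structure = character(),
                                                   metric = character(),
                                                   value = numeric()),
                          provenance = "clinical")
  new("PatientRecord", structures = structures, achievedDVH = achievedDVH,
      provenance = provenance)

#' @describeIn patientID patient ID of a PatientRecord
#' @export
setMethod("patientID", "PatientRecord", function(x) x@structures@patientID)
#' @describeIn structureNames structures of a PatientRecord
#' @export
setMethod("structureNames", "PatientRecord",
          function(x) names(x@structures@structures))
#' @describeIn getStructure extract a mask from a PatientRecord
#' @export
setMethod("getStructure", "PatientRecord",
          function(x, name) getStructure(x@structures, name))
#' @describeIn achievedDVH achieved DVH table of a PatientRecord
#' @export
setMethod("achievedDVH", "PatientRecord", function(x) x@achievedDVH)

# achieved value lookup; NA when absent
.achievedValue <- function(record, structure, metric) {
  df <- record@achievedDVH
  i <- which(df$structure == structure & df$metric == metric)
  if (length(i) == 0L) NA_real_ else df$value[i[1L]]
}

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord '%s' (%s): %s\n", patientID(object),
              object@provenance,
              paste(structureNames(object), collapse = ", ")))
  if (nrow(object@achievedDVH))
    cat(sprintf("  achieved: %s\n",
                paste(sprintf("%s %s = %.2f", object@achievedDVH$structure,
                              object@achievedDVH$metric,
                              object@achievedDVH$value), collapse = "; ")))
})

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`.
#'
#' @param a,b [BinaryMask] objects on one grid; at least one nonempty.
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' g <- makeGrid(c(8, 8, 8), 2)
#' v <- array(FALSE, gridShape(g)); v[2:5, 2:5, 2:5] <- TRUE
#' dice(binaryMask(v, g), binaryMask(v, g))  # 1
#' @export
dice <- function(a, b) {
  if (!sameGrid(a@grid, b@grid))
    stop("dice requires both masks on the same grid")
  na <- sum(a@values); nb <- sum(b@values)
  if (na + nb == 0L)
    stop("DSC is undefined for two empty masks (0/0)")
  2 * sum(a@values & b@values) / (na + nb)
}

#' Score one database candidate against a test patient
#'
#' Registers the candidate's PTV to the test patient's PTV
#' (translation-only), applies the single resulting translation to the
#' candidate's PTV, rectum, and bladder, and returns the Dice coefficient of
#' each against the test patient's corresponding structure. The one shared
#' translation preserves the candidate's PTV-OAR geometric relationship,
#' which is the similarity the method targets.
#'
#' @param test,candidate [PatientRecord] objects containing PTV, rectum and
#'   bladder on a common grid.
#' @return a [SimilarityRecord].
#' @export
scorePair <- function(test, candidate) {
  need <- c("PTV", "rectum", "bladder")
  for (nm in need) {
    if (!nm %in% structureNames(test))
      stop("test patient lacks structure '", nm, "'")
    if (!nm %in% structureNames(candidate))
      stop("candidate ", patientID(candidate), " lacks structure '", nm, "'")
  }
  reg <- registerTranslation(getStructure(test, "PTV"),
                             getStructure(candidate, "PTV"))
  t <- translation(reg)
  d <- vapply(need, function(nm)
    dice(getStructure(test, nm),
         applyTranslation(getStructure(candidate, nm), t)),
    numeric(1))
  names(d) <- need
  new("SimilarityRecord", patientID = patientID(candidate),
      translation = t, dsc = d)
}

#' @describeIn translation translation of a SimilarityRecord
#' @export
setMethod("translation", "SimilarityRecord", function(x) x@translation)

setMethod("show", "SimilarityRecord", function(object) {
  cat(sprintf(
    "SimilarityRecord '%s': t = (%d, %d, %d); DSC ptv %.3f rectum %.3f bladder %.3f\n",
    object@patientID, object@translation[1L], object@translation[2L],
    object@translation[3L], object@dsc[["PTV"]], object@dsc[["rectum"]],
    object@dsc[["bladder"]]))
})

# rank patient ids by a score column, descending, ties by id ascending
.rankIDs <- function(df, column)
  df$patient_id[order(-df[[column]], df$patient_id)]

#' Two-stage anatomically-similar patient selection
#'
#' Scores every database patient against the test patient ([scorePair()]),
#' keeps the `kPtv` patients with the highest PTV Dice coefficient, then —
#' independently for the rectum and for the bladder — keeps the `kOar`
#' patients with the highest organ Dice among those. The derived V50Gy
#' constraint per organ is the minimum achieved V50Gy over its matched
#' patients. All ties are broken by ascending patient ID. A database entry
#' whose ID equals the test patient's is excluded (leave-one-out).
#'
#' @param test a [PatientRecord].
#' @param database list of [PatientRecord].
#' @param kPtv,kOar integers (defaults 20 and 3).
#' @return a [MatchSelection].
#' @export
matchPatient <- function(test, database, kPtv = 20L, kOar = 3L) {
  kPtv <- as.integer(kPtv); kOar <- as.integer(kOar)
  if (kOar < 1L || kPtv < kOar)
    stop("need kPtv >= kOar >= 1")
  ids <- vapply(database, patientID, character(1))
  keep <- ids != patientID(test)
  database <- database[keep]; ids <- ids[keep]
  if (anyDuplicated(ids))
    stop("duplicate patient IDs in database")
  if (length(database) < kPtv)
    stop("database holds ", length(database), " candidates but kPtv = ",
         kPtv, "; lower kPtv (or enlarge the database)")
  recs <- lapply(database, function(cand) scorePair(test, cand))
  tab <- data.frame(
    patient_id  = vapply(recs, function(r) r@patientID, character(1)),
    dsc_ptv     = vapply(recs, function(r) r@dsc[["PTV"]], numeric(1)),
    dsc_rectum  = vapply(recs, function(r) r@dsc[["rectum"]], numeric(1)),
    dsc_bladder = vapply(recs, function(r) r@dsc[["bladder"]], numeric(1)),
    tu = vapply(recs, function(r) r@translation[1L], integer(1)),
    tv = vapply(recs, function(r) r@translation[2L], integer(1)),
    tw = vapply(recs, function(r) r@translation[3L], integer(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$patient_id), , drop = FALSE]
  rownames(tab) <- NULL
  ptvTop <- .rankIDs(tab, "dsc_ptv")[seq_len(kPtv)]
  sub <- tab[tab$patient_id %in% ptvTop, , drop = FALSE]
  rectumTop  <- .rankIDs(sub, "dsc_rectum")[seq_len(kOar)]
  bladderTop <- .rankIDs(sub, "dsc_bladder")[seq_len(kOar)]
  byID <- stats::setNames(database, ids)
  minAchieved <- function(top, organ) {
    vals <- vapply(top, function(id)
      .achievedValue(byID[[id]], organ, "V50Gy"), numeric(1))
    if (anyNA(vals)) NA_real_ else min(vals)
  }
  cons <- c(rectum  = minAchieved(rectumTop, "rectum"),
            bladder = minAchieved(bladderTop, "bladder"))
  new("MatchSelection", scoreTable = tab, ptvTop = ptvTop,
      rectumTop = rectumTop, bladderTop = bladderTop, constraints = cons)
}

#' @describeIn constraints derived V50Gy constraints of a MatchSelection
#' @export
setMethod("constraints", "MatchSelection", function(x) x@constraints)
#' @describeIn scoreTable full score table of a MatchSelection
#' @export
setMethod("scoreTable", "MatchSelection", function(x) x@scoreTable)

setMethod("show", "MatchSelection", function(object) {
  cat(sprintf("MatchSelection: %d scored, top-%d PTV match\n",
              nrow(object@scoreTable), length(object@ptvTop)))
  cat("  rectum top: ", paste(object@rectumTop, collapse = ", "), "\n")
  cat("  bladder top:", paste(object@bladderTop, collapse = ", "), "\n")
  cat(sprintf("  constraints: rectum V50Gy %.2f%%, bladder V50Gy %.2f%%\n",
              object@constraints[["rectum"]],
              object@constraints[["bladder"]]))
})

#' The institutional optimization-objective template
#'
#' The protocol objective set used for every plan: PTV uniform dose 50 Gy,
#' Dmin 49.5 Gy, Dmax 52 Gy, minimum V50Gy 96%; rectum and bladder V45Gy 45%
#' (the two rows replaced by personalized V50Gy constraints in
#' [deriveConstraints()]); femoral heads V45Gy 5%; small intestine V45Gy 10%
#' and Dmax 50 Gy; spinal cord Dmax 42 Gy.
#'
#' @return data.frame with columns `structure`, `metric`, `value`, `units`.
#' @export
objectiveTemplate <- function() {
  data.frame(
    structure = c("PTV", "PTV", "PTV", "PTV", "rectum", "bladder",
                  "femoral_head_L", "femoral_head_R", "small_intestine",
                  "small_intestine", "spinal_cord"),
    metric = c("MinimumV50Gy", "Dmax", "Dmin", "UniformDose", "V45Gy",
               "V45Gy", "V45Gy", "V45Gy", "V45Gy", "Dmax", "Dmax"),
    value = c(96, 52, 49.5, 50, 45, 45, 5, 5, 10, 50, 42),
    units = c("%", "Gy", "Gy", "Gy", "%", "%", "%", "%", "%", "Gy", "Gy"),
    stringsAsFactors = FALSE)
}

#' Personalized optimization objectives from a match selection
#'
#' Copies the protocol template ([objectiveTemplate()]) and replaces the
#' rectum and bladder volume-constraint rows with the personalized V50Gy
#' constraints: the minimum achieved V50Gy over each organ's matched
#' patients. All other rows are kept verbatim.
#'
#' @param selection a [MatchSelection].
#' @param database list of [PatientRecord] (used to re-read achieved values
#'   when the selection carries none).
#' @return data.frame in the [objectiveTemplate()] layout.
#' @export
deriveConstraints <- function(selection, database) {
  byID <- stats::setNames(database,
                          vapply(database, patientID, character(1)))
  fetch <- function(top, organ) {
    vals <- vapply(top, function(id) {
      if (is.null(byID[[id]]))
        stop("matched patient '", id, "' not present in database")
      v <- .achievedValue(byID[[id]], organ, "V50Gy")
      if (is.na(v))
        stop("patient '", id, "' has no achieved ", organ, " V50Gy value")
      v
    }, numeric(1))
    min(vals)
  }
  rectumV50  <- fetch(selection@rectumTop, "rectum")
  bladderV50 <- fetch(selection@bladderTop, "bladder")
  obj <- objectiveTemplate()
  i <- which(obj$structure == "rectum")
  obj$metric[i] <- "V50Gy"; obj$value[i] <- rectumV50
  i <- which(obj$structure == "bladder")
  obj$metric[i] <- "V50Gy"; obj$value[i] <- bladderV50
  obj
}
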