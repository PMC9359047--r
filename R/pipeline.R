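#' @include io.R synthetic.R dvh.R
NULL

#' Construct a pipeline configuration
#'
#' @param gridShape integer(3), common grid shape (default 96 x 96 x 64).
#' @param spacing common isotropic grid spacing, mm (default 2.5). All
#'   patients are resampled to this shared grid before registration.
#' @param origin grid origin, mm; `NULL` centers the grid on (0,0,0).
#' @param kPtv,kOar two-stage selection sizes (defaults 20 and 3).
#' @param binWidth DVH bin width, Gy (default 0.05).
#' @param aliasTable structure alias table (named character vector).
#' @param seed integer seed for randomized commands.
#' @return a [PipelineConfig].
#' @export
pipelineConfig <- function(gridShape = c(96L, 96L, 64L), spacing = 2.5,
                           origin = NULL, kPtv = 20L, kOar = 3L,
                           binWidth = 0.05,
                           aliasTable = defaultStructureAliases(),
                           seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin))
    origin <- -(as.integer(gridShape) - 1L) * spacing / 2
  new("PipelineConfig", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      kPtv = as.integer(kPtv), kOar = as.integer(kOar),
      binWidth = binWidth, aliasTable = aliasTable, seed = as.integer(seed))
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized fields: `grid_shape`, `spacing`, `origin`, `k_ptv`, `k_oar`,
#' `bin_width`, `aliases` (object mapping alias to canonical name), `seed`.
#' Missing fields take the [pipelineConfig()] defaults.
#'
#' @param path JSON config file.
#' @return a [PipelineConfig].
#' @export
readPipelineConfig <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  al <- defaultStructureAliases()
  if (!is.null(doc$aliases)) {
    extra <- unlist(doc$aliases)
    al[.normalizeROIName(names(extra))] <- unname(extra)
  }
  pipelineConfig(
    gridShape = if (is.null(doc$grid_shape)) c(96L, 96L, 64L) else doc$grid_shape,
    spacing = if (is.null(doc$spacing)) 2.5 else doc$spacing,
    origin = doc$origin,
    kPtv = if (is.null(doc$k_ptv)) 20L else doc$k_ptv,
    kOar = if (is.null(doc$k_oar)) 3L else doc$k_oar,
    binWidth = if (is.null(doc$bin_width)) 0.05 else doc$bin_width,
    aliasTable = al,
    seed = if (is.null(doc$seed)) 1L else doc$seed)
}

.configGrid <- function(config)
  makeGrid(config@gridShape, config@spacing, config@origin)

#' Simulate a synthetic patient cohort into a directory
#'
#' Writes one mask-bundle JSON per patient (masks + achieved DVH parameters
#' from the synthetic dose model) plus an `achieved_dvh.csv` summary.
#'
#' @param n cohort size.
#' @param outDir output directory (created if needed).
#' @param config a [PipelineConfig]; its grid and seed are used.
#' @param base [PhantomParams] population parameters (grid fields are
#'   overridden by the config grid).
#' @param doseParams a [DoseModelParams].
#' @return invisibly, the vector of written file paths.
#' @export
simulateCohort <- function(n, outDir, config = pipelineConfig(),
                           base = phantomParams(),
                           doseParams = doseModelParams()) {
  base@gridShape <- config@gridShape
  base@spacing <- config@spacing
  db <- makeDatabase(n, base, doseParams, seed = config@seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(db, function(rec) {
    p <- file.path(outDir, paste0(patientID(rec), ".masks.json"))
    writePatientRecord(rec, p)
    p
  }, character(1))
  summary <- do.call(rbind, lapply(db, function(rec) {
    df <- achievedDVH(rec)
    df$patient_id <- patientID(rec)
    df[, c("patient_id", "structure", "metric", "value")]
  }))
  utils::write.csv(summary, file.path(outDir, "achieved_dvh.csv"),
                   row.names = FALSE)
  invisible(paths)
}

# load one patient from a file of either supported format, resampled onto
# the common grid; NULL (with a warning) when the PTV is absent
.loadPatientFile <- function(path, config) {
  grid <- .configGrid(config)
  rec <- if (grepl("\\.contours\\.json$", path)) {
    st <- readContourSet(path, grid, config@aliasTable)
    patientRecord(st, provenance = "clinical")
  } else {
    readPatientRecord(path)
  }
  st <- rec@structures
  if (!sameGrid(voxelGrid(st), grid)) {
    masks <- lapply(st@structures, resampleMask, targetGrid = grid)
    rec@structures <- structureSet(patientID(rec), masks)
  }
  rec
}

#' Build a cached patient database from an input directory
#'
#' Scans `inputDir` for per-patient files (`*.contours.json` or
#' `*.masks.json`, plus optional `<id>.dose.json`), resamples every
#' structure onto the common grid, computes achieved rectum/bladder V50Gy
#' where a dose file is present, writes one mask bundle per patient into
#' `outDir` and a deterministic `manifest.json`. Patients without a PTV are
#' skipped with a warning.
#'
#' @param inputDir input directory.
#' @param outDir output database directory.
#' @param config a [PipelineConfig].
#' @return invisibly, the manifest as a list.
#' @export
buildDatabase <- function(inputDir, outDir, config = pipelineConfig()) {
  files <- sort(c(list.files(inputDir, "\\.contours\\.json$",
                             full.names = TRUE),
                  list.files(inputDir, "\\.masks\\.json$",
                             full.names = TRUE)))
  if (!length(files)) stop("no patient files found in '", inputDir, "'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- .configGrid(config)
  entries <- list()
  for (f in files) {
    rec <- tryCatch(.loadPatientFile(f, config), error = function(e) {
      warning("skipping '", f, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    doseFile <- file.path(dirname(f),
                          paste0(patientID(rec), ".dose.json"))
    if (file.exists(doseFile)) {
      dose <- readDoseGrid(doseFile, grid)
      rec@achievedDVH <- .achievedTable(rec@structures, dose, 50,
                                        config@binWidth)
    }
    out <- file.path(outDir, paste0(patientID(rec), ".masks.json"))
    writePatientRecord(rec, out)
    get50 <- function(organ) .achievedValue(rec, organ, "V50Gy")
    entries[[patientID(rec)]] <- list(
      patient_id = patientID(rec), file = basename(out),
      structures = structureNames(rec),
      rectum_V50Gy = get50("rectum"), bladder_V50Gy = get50("bladder"))
  }
  if (!length(entries)) stop("no usable patients (every file lacked a PTV?)")
  entries <- entries[order(names(entries))]
  manifest <- list(
    grid = list(shape = grid@shape, spacing = grid@spacing,
                origin = grid@origin),
    n_patients = length(entries),
    patients = unname(entries))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load every patient record of a database directory
#' @param databaseDir directory written by [buildDatabase()] or
#'   [simulateCohort()].
#' @return list of [PatientRecord], sorted by patient ID.
#' @export
loadDatabase <- function(databaseDir) {
  files <- sort(list.files(databaseDir, "\\.masks\\.json$",
                           full.names = TRUE))
  if (!length(files))
    stop("no mask bundles found in '", databaseDir, "'")
  lapply(files, readPatientRecord)
}

#' Match a test patient against a database directory and emit the artifacts
#'
#' Runs the two-stage similar-patient selection and writes three files into
#' `outDir`: `score_table.csv` (per-candidate DSC and translation),
#' `match_selection.json` (ranked selections and derived V50Gy constraints)
#' and `objectives.json` (the personalized optimization objective set, a
#' TPS-agnostic mirror of the protocol template). Per-patient registration
#' wall time is logged via `message()`.
#'
#' @param test a [PatientRecord] or the path of a patient file.
#' @param databaseDir database directory.
#' @param outDir output directory.
#' @param config a [PipelineConfig] (supplies `kPtv`, `kOar`, the grid).
#' @return the [MatchSelection], invisibly.
#' @export
runMatch <- function(test, databaseDir, outDir, config = pipelineConfig()) {
  if (is.character(test)) test <- .loadPatientFile(test, config)
  db <- loadDatabase(databaseDir)
  nCand <- sum(vapply(db, patientID, character(1)) != patientID(test))
  if (nCand < config@kPtv)
    stop("database provides ", nCand, " candidates but k_ptv = ",
         config@kPtv, "; add patients or lower k_ptv in the config")
  t0 <- proc.time()[["elapsed"]]
  sel <- matchPatient(test, db, kPtv = config@kPtv, kOar = config@kOar)
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf(
    "matched '%s' against %d patients in %.1f s (%.2f s/patient)",
    patientID(test), nCand, dt, dt / nCand))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scoreTable(sel), file.path(outDir, "score_table.csv"),
                   row.names = FALSE)
  selDoc <- list(test_patient = patientID(test),
                 k_ptv = config@kPtv, k_oar = config@kOar,
                 ptv_top = sel@ptvTop, rectum_top = sel@rectumTop,
                 bladder_top = sel@bladderTop,
                 constraints = as.list(constraints(sel)))
  jsonlite::write_json(selDoc, file.path(outDir, "match_selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  obj <- deriveConstraints(sel, db)
  jsonlite::write_json(list(test_patient = patientID(test),
                            objectives = obj),
                       file.path(outDir, "objectives.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(sel)
}

#' Evaluate a plan from files and emit metric and goal reports
#'
#' Reads a dose file and a patient structure file, resamples both onto the
#' common grid, computes the plan metrics and goal flags with
#' [evaluatePlan()], and writes `plan_metrics.csv` and `goal_report.json`
#' into `outDir`.
#'
#' @param doseFile dose JSON file.
#' @param structFile patient file (`*.contours.json` or `*.masks.json`).
#' @param outDir output directory.
#' @param config a [PipelineConfig].
#' @return the [evaluatePlan()] result, invisibly.
#' @export
evaluatePlanFiles <- function(doseFile, structFile, outDir,
                              config = pipelineConfig()) {
  rec <- .loadPatientFile(structFile, config)
  dose <- readDoseGrid(doseFile, .configGrid(config))
  res <- evaluatePlan(dose, rec@structures, binWidth = config@binWidth)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$metrics, file.path(outDir, "plan_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(patient_id = patientID(rec),
                            goals = res$goals),
                       file.path(outDir, "goal_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(res)
}
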