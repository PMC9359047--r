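#' @include grid.R
NULL

#' Cumulative dose-volume histogram of one structure
#'
#' The volume fraction at dose edge `d` is
#' `100 * #(structure voxels with dose >= d) / |structure|` (inclusive
#' thresholding). Edges run from 0 Gy past the maximum structure dose in
#' steps of `binWidth`. The sorted per-voxel doses are retained so
#' [vAtDose()] is exact.
#'
#' @param dose a [DoseGrid].
#' @param mask a nonempty [BinaryMask] on the same grid.
#' @param binWidth histogram bin width in Gy (default 0.05).
#' @param structure structure name carried on the curve.
#' @return a [DVHCurve].
#' @export
cumulativeDVH <- function(dose, mask, binWidth = 0.05, structure = "") {
  if (!sameGrid(dose@grid, mask@grid))
    stop("dose and mask must share one grid")
  if (sum(mask@values) == 0L)
    stop("cumulative DVH of an empty structure is undefined")
  d <- sort(dose@dose[mask@values])
  n <- length(d)
  edges <- seq(0, max(d) + binWidth, by = binWidth)
  # count of doses >= edge = n - count(doses < edge)
  below <- findInterval(edges, d, left.open = TRUE)
  vf <- 100 * (n - below) / n
  new("DVHCurve", doseEdges = edges, volumeFraction = vf,
      structure = structure,
      totalVolumeCc = n * prod(mask@grid@spacing) / 1000,
      voxelDoses = d)
}

#' Volume fraction receiving at least a dose (VxGy)
#'
#' Exact when the curve retains the raw voxel doses (the default from
#' [cumulativeDVH()]); otherwise linear interpolation between bin edges.
#'
#' @param curve a [DVHCurve].
#' @param d dose threshold in Gy (>= 0).
#' @return percent in `[0, 100]`.
#' @export
vAtDose <- function(curve, d) {
  stopifnot(d >= 0)
  if (length(curve@voxelDoses)) {
    n <- length(curve@voxelDoses)
    below <- findInterval(d, curve@voxelDoses, left.open = TRUE)
    return(100 * (n - below) / n)
  }
  if (d > max(curve@doseEdges)) return(0)
  stats::approx(curve@doseEdges, curve@volumeFraction, xout = d,
                rule = 2)$y
}

#' Dose received by the hottest v% of a structure (Dx)
#'
#' The smallest dose `d` at which the cumulative volume fraction drops to
#' `v` percent, linearly interpolated between the bracketing histogram
#' edges: `D98` is `dAtVolume(curve, 98)`, `D2` is `dAtVolume(curve, 2)`.
#'
#' @param curve a [DVHCurve].
#' @param v percent in `(0, 100]`.
#' @return dose in Gy.
#' @export
dAtVolume <- function(curve, v) {
  stopifnot(v > 0, v <= 100)
  vf <- curve@volumeFraction; ed <- curve@doseEdges
  k <- which(vf <= v)
  if (!length(k)) return(ed[length(ed)])
  k <- k[1L]
  if (k == 1L) return(ed[1L])
  if (vf[k - 1L] == vf[k]) return(ed[k])
  ed[k - 1L] + (ed[k] - ed[k - 1L]) * (vf[k - 1L] - v) / (vf[k - 1L] - vf[k])
}

#' Maximum structure dose (single-voxel Dmax)
#' @param curve a [DVHCurve] retaining voxel doses.
#' @return Gy.
#' @export
doseMax <- function(curve) {
  if (length(curve@voxelDoses)) return(max(curve@voxelDoses))
  curve@doseEdges[max(which(curve@volumeFraction > 0))]
}

#' Homogeneity index of a target DVH
#'
#' `HI = 100 * (D2 - D98) / prescription` (percent); 0 for a perfectly
#' uniform dose, larger for less homogeneous coverage.
#'
#' @param curve a [DVHCurve] of the target.
#' @param prescription prescription dose in Gy (> 0), default 50.
#' @return percent.
#' @export
homogeneityIndex <- function(curve, prescription = 50) {
  stopifnot(prescription > 0)
  100 * (dAtVolume(curve, 2) - dAtVolume(curve, 98)) / prescription
}

# plan-evaluation goals: metric, structure, comparator, limit
.planGoals <- function() {
  data.frame(
    structure = c("PTV", "rectum", "bladder", "femoral_head_L",
                  "femoral_head_R", "small_intestine", "small_intestine",
                  "spinal_cord"),
    metric = c("V50Gy", "V50Gy", "V50Gy", "V50Gy", "V50Gy", "V50Gy",
               "Dmax", "Dmax"),
    comparator = c(">", "<", "<", "<", "<", "<", "<", "<"),
    goal = c(96, 50, 50, 10, 10, 10, 52, 45),
    units = c("%", "%", "%", "%", "%", "%", "Gy", "Gy"),
    stringsAsFactors = FALSE)
}

#' Evaluate a plan: dose metrics and pass/fail against the clinical goals
#'
#' Computes the standard plan-comparison metrics — PTV V50Gy, homogeneity
#' index, D98, D95, D2; rectum, bladder and femoral-head V50Gy; small
#' intestine V50Gy and Dmax; spinal cord Dmax — for every structure present,
#' and flags each metric against the evaluation goals (PTV V50Gy > 96%;
#' rectum/bladder V50Gy < 50%; femoral heads and small intestine
#' V50Gy < 10%; small intestine Dmax < 52 Gy; cord Dmax < 45 Gy). Absent
#' structures are reported with `NA` values and a `missing` flag, not as
#' failures.
#'
#' @param dose a [DoseGrid].
#' @param structures a [StructureSet] on the dose grid (PTV required).
#' @param prescription prescription dose in Gy (default 50).
#' @param binWidth DVH bin width in Gy.
#' @return list with elements `metrics` (data.frame `structure`, `metric`,
#'   `value`, `units`) and `goals` (data.frame adding `goal`, `comparator`,
#'   `status` = pass/fail/missing).
#' @export
evaluatePlan <- function(dose, structures, prescription = 50,
                         binWidth = 0.05) {
  if (!"PTV" %in% structureNames(structures))
    stop("plan evaluation requires a PTV structure")
  curves <- list()
  for (nm in structureNames(structures)) {
    m <- getStructure(structures, nm)
    if (sum(m@values) > 0L)
      curves[[nm]] <- cumulativeDVH(dose, m, binWidth, structure = nm)
  }
  if (is.null(curves$PTV)) stop("PTV mask is empty")
  rows <- list()
  add <- function(structure, metric, value, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, metric = metric, value = value, units = units,
      stringsAsFactors = FALSE)
  ptv <- curves$PTV
  add("PTV", "V50Gy", vAtDose(ptv, prescription), "%")
  add("PTV", "HI", homogeneityIndex(ptv, prescription), "%")
  add("PTV", "D98", dAtVolume(ptv, 98), "Gy")
  add("PTV", "D95", dAtVolume(ptv, 95), "Gy")
  add("PTV", "D2", dAtVolume(ptv, 2), "Gy")
  for (nm in c("rectum", "bladder", "femoral_head_L", "femoral_head_R",
               "small_intestine")) {
    v <- if (is.null(curves[[nm]])) NA_real_
         else vAtDose(curves[[nm]], prescription)
    add(nm, "V50Gy", v, "%")
  }
  for (nm in c("small_intestine", "spinal_cord")) {
    v <- if (is.null(curves[[nm]])) NA_real_ else doseMax(curves[[nm]])
    add(nm, "Dmax", v, "Gy")
  }
  metrics <- do.call(rbind, rows)
  goals <- merge(.planGoals(), metrics[, c("structure", "metric", "value")],
                 by = c("structure", "metric"), sort = FALSE)
  goals$status <- ifelse(
    is.na(goals$value), "missing",
    ifelse(goals$comparator == ">",
           ifelse(goals$value > goals$goal, "pass", "fail"),
           ifelse(goals$value < goals$goal, "pass", "fail")))
  goals <- goals[order(goals$structure, goals$metric), , drop = FALSE]
  rownames(goals) <- NULL
  list(metrics = metrics, goals = goals)
}

#' Paired comparison of two plan cohorts
#'
#' For every metric shared by the two cohorts, computes the paired
#' differences `a - b` (paired by list position), their mean and standard
#' deviation, the paired t statistic `t = mean / (sd / sqrt(n))` and the
#' two-sided p-value from the t distribution with `n - 1` degrees of
#' freedom. Degenerate cases: all differences zero gives `t = 0, p = 1`;
#' zero-variance nonzero differences are flagged `degenerate` with `p = 0`.
#'
#' @param a,b lists (equal length >= 2) of metric data.frames as returned in
#'   `evaluatePlan()$metrics`.
#' @return data.frame with one row per (structure, metric): `mean_diff`,
#'   `sd_diff`, `t`, `p`, `n`, `note`.
#' @export
comparePlanCohorts <- function(a, b) {
  if (length(a) != length(b))
    stop("cohorts must have equal length (paired by index)")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired plans")
  key <- function(df) paste(df$structure, df$metric)
  k0 <- key(a[[1L]])
  pull <- function(df, k) df$value[match(k, key(df))]
  diffs <- vapply(seq_len(n),
                  function(i) pull(a[[i]], k0) - pull(b[[i]], k0),
                  numeric(length(k0)))
  diffs <- matrix(diffs, nrow = length(k0))
  out <- data.frame(structure = a[[1L]]$structure, metric = a[[1L]]$metric,
                    mean_diff = NA_real_, sd_diff = NA_real_, t = NA_real_,
                    p = NA_real_, n = n, note = "", stringsAsFactors = FALSE)
  for (i in seq_along(k0)) {
    d <- diffs[i, ]
    if (anyNA(d)) { out$note[i] <- "missing values"; next }
    m <- mean(d); s <- stats::sd(d)
    out$mean_diff[i] <- m; out$sd_diff[i] <- s
    if (s == 0) {
      if (m == 0) { out$t[i] <- 0; out$p[i] <- 1 }
      else { out$t[i] <- Inf * sign(m); out$p[i] <- 0
             out$note[i] <- "degenerate: zero-variance nonzero difference" }
    } else {
      tt <- m / (s / sqrt(n))
      out$t[i] <- tt
      out$p[i] <- 2 * stats::pt(-abs(tt), df = n - 1)
    }
  }
  out
}

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf(
    "DVHCurve '%s': %.1f cc, max %.2f Gy, V50Gy = %.1f%%\n",
    object@structure, object@totalVolumeCc, doseMax(object),
    vAtDose(object, 50)))
})

#' Export a DVH curve as a data.frame
#' @param curve a [DVHCurve].
#' @return data.frame with columns `dose_gy`, `volume_pct`.
#' @export
dvhTable <- function(curve)
  data.frame(dose_gy = curve@doseEdges, volume_pct = curve@volumeFraction)
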