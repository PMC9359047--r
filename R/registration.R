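#' @include grid.R
NULL

# bounding box of a mask: list(lo = integer(3) 1-based, values = cropped array)
.cropToBox <- function(values) {
  idx <- which(values, arr.ind = TRUE)
  lo <- c(min(idx[, 1L]), min(idx[, 2L]), min(idx[, 3L]))
  hi <- c(max(idx[, 1L]), max(idx[, 2L]), max(idx[, 3L]))
  list(lo = as.integer(lo),
       values = values[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L],
                       drop = FALSE])
}

# linear cross-correlation of two cropped boxes via zero-padded 3D FFT.
# Returns list(scores = rounded integer counts over the full lag range of the
# boxes, tmin = integer(3) translation of the first array index).
# Convention: scores[i,j,k] = sum_x fixed(x) * moving(x - t) with
# t = tmin + (i,j,k) - 1, i.e. the overlap after translating `moving` by t.
.fftBoxCorrelation <- function(fx, mv, loF, loM) {
  df <- dim(fx); dm <- dim(mv)
  full <- df + dm - 1L
  P <- vapply(full, function(n) stats::nextn(n, c(2L, 3L, 5L)), integer(1))
  padF <- array(0, P); padF[seq_len(df[1]), seq_len(df[2]), seq_len(df[3])] <- fx
  padM <- array(0, P); padM[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- mv
  C <- Re(stats::fft(stats::fft(padF) * Conj(stats::fft(padM)),
                     inverse = TRUE)) / prod(P)
  # circular lag k-1 (0-based); linear lags t' in [-(dm-1), df-1];
  # reorder so axis index i corresponds to t' = i - dm
  ord <- lapply(1:3, function(a) {
    neg <- if (dm[a] > 1L) (P[a] - dm[a] + 2L):P[a] else integer(0)
    c(neg, 1L:df[a])
  })
  C <- C[ord[[1L]], ord[[2L]], ord[[3L]], drop = FALSE]
  # box lag t' relates to the full-grid translation t by t = t' + loF - loM
  list(scores = round(C), tmin = -(dm - 1L) + (loF - loM))
}

#' Spatial correlation of two binary masks over all translations (FFT)
#'
#' Computes the overlap voxel count `S(u,v,w)` between the fixed mask and the
#' moving mask translated by every candidate integer-voxel offset `(u,v,w)`,
#' over the full linear-correlation range `-(Nm-1) .. (Nf-1)` per axis. Both
#' masks are cropped to their bounding boxes, zero-padded to the full
#' linear-correlation size (no circular wrap-around), transformed with the
#' FFT, multiplied with one conjugated, inverse-transformed, and rounded to
#' the nearest integer.
#'
#' @param fixed,moving [BinaryMask] objects sharing one voxel spacing
#'   (shapes may differ); both must be nonempty.
#' @return a [ScoreVolume].
#' @seealso [bruteForceCorrelation()] for the exact spatial-domain oracle,
#'   [registerTranslation()] for the argmax with deterministic tie-breaks.
#' @export
correlationMap <- function(fixed, moving) {
  .checkRegistrable(fixed, moving)
  Nf <- fixed@grid@shape; Nm <- moving@grid@shape
  bf <- .cropToBox(fixed@values); bm <- .cropToBox(moving@values)
  cc <- .fftBoxCorrelation(bf$values, bm$values, bf$lo, bm$lo)
  uOff <- seq.int(-(Nm[1L] - 1L), Nf[1L] - 1L)
  vOff <- seq.int(-(Nm[2L] - 1L), Nf[2L] - 1L)
  wOff <- seq.int(-(Nm[3L] - 1L), Nf[3L] - 1L)
  scores <- array(0, c(length(uOff), length(vOff), length(wOff)))
  d <- dim(cc$scores)
  at <- lapply(1:3, function(a)
    (cc$tmin[a] - c(-(Nm[a] - 1L))) + seq_len(d[a]))
  scores[at[[1L]], at[[2L]], at[[3L]]] <- pmax(cc$scores, 0)
  new("ScoreVolume", scores = scores,
      uOffsets = as.integer(uOff), vOffsets = as.integer(vOff),
      wOffsets = as.integer(wOff), spacing = fixed@grid@spacing)
}

#' Spatial correlation by direct summation (oracle)
#'
#' Exact integer overlap counts for every candidate translation, computed in
#' the spatial domain without any FFT: every pair of occupied voxels (one in
#' each mask) contributes one count at their index-difference translation.
#' Intended for masks up to about 24 voxels per side; cost grows with
#' `|fixed| * |moving|`.
#'
#' @inheritParams correlationMap
#' @return a [ScoreVolume] identical (elementwise) to [correlationMap()].
#' @export
bruteForceCorrelation <- function(fixed, moving) {
  .checkRegistrable(fixed, moving)
  Nf <- fixed@grid@shape; Nm <- moving@grid@shape
  cf <- which(fixed@values, arr.ind = TRUE)
  cm <- which(moving@values, arr.ind = TRUE)
  nU <- Nf[1L] + Nm[1L] - 1L
  nV <- Nf[2L] + Nm[2L] - 1L
  nW <- Nf[3L] + Nm[3L] - 1L
  # translation t = fixed index - moving index; shift to 1-based bins
  du <- outer(cf[, 1L], cm[, 1L], "-") + Nm[1L]
  dv <- outer(cf[, 2L], cm[, 2L], "-") + Nm[2L]
  dw <- outer(cf[, 3L], cm[, 3L], "-") + Nm[3L]
  lin <- du + (dv - 1L) * nU + (dw - 1L) * nU * nV
  counts <- tabulate(lin, nbins = nU * nV * nW)
  new("ScoreVolume", scores = array(as.numeric(counts), c(nU, nV, nW)),
      uOffsets = as.integer(seq.int(-(Nm[1L] - 1L), Nf[1L] - 1L)),
      vOffsets = as.integer(seq.int(-(Nm[2L] - 1L), Nf[2L] - 1L)),
      wOffsets = as.integer(seq.int(-(Nm[3L] - 1L), Nf[3L] - 1L)),
      spacing = fixed@grid@spacing)
}

.checkRegistrable <- function(fixed, moving) {
  if (!is(fixed, "BinaryMask") || !is(moving, "BinaryMask"))
    stop("fixed and moving must be BinaryMask objects")
  if (any(abs(fixed@grid@spacing - moving@grid@spacing) > 1e-6))
    stop("fixed and moving masks must share one voxel spacing")
  if (sum(fixed@values) == 0L || sum(moving@values) == 0L)
    stop("registration of an empty mask has no meaningful optimum")
  invisible(TRUE)
}

# deterministic argmax with ties broken by (1) smallest Euclidean
# displacement in mm, (2) lexicographic order on (u, v, w)
.pickTranslation <- function(cand, spacingMm) {
  mm2 <- (cand[, 1L] * spacingMm[1L])^2 + (cand[, 2L] * spacingMm[2L])^2 +
         (cand[, 3L] * spacingMm[3L])^2
  cand <- cand[mm2 == min(mm2), , drop = FALSE]
  o <- order(cand[, 1L], cand[, 2L], cand[, 3L])
  as.integer(cand[o[1L], ])
}

#' Register a moving PTV mask to a fixed PTV mask (translation only)
#'
#' Finds the integer-voxel translation of the moving mask that maximizes the
#' voxel overlap with the fixed mask (equivalently, minimizes the binary
#' squared-error). Ties are broken deterministically: smallest Euclidean
#' displacement in mm first, then lexicographic order on `(u, v, w)`.
#'
#' @inheritParams correlationMap
#' @return a [RegistrationResult].
#' @examples
#' g <- makeGrid(c(16, 16, 16), 2)
#' a <- array(FALSE, gridShape(g)); a[5:8, 5:8, 5:8] <- TRUE
#' b <- array(FALSE, gridShape(g)); b[6:9, 5:8, 5:8] <- TRUE  # shifted +1 in x
#' r <- registerTranslation(binaryMask(a, g), binaryMask(b, g))
#' translation(r)  # (-1, 0, 0): moving must move back to align
#' @export
registerTranslation <- function(fixed, moving) {
  .checkRegistrable(fixed, moving)
  bf <- .cropToBox(fixed@values); bm <- .cropToBox(moving@values)
  cc <- .fftBoxCorrelation(bf$values, bm$values, bf$lo, bm$lo)
  best <- max(cc$scores)
  idx <- which(cc$scores == best, arr.ind = TRUE)
  cand <- sweep(idx - 1L, 2L, cc$tmin, "+")   # index -> translation
  t <- .pickTranslation(cand, fixed@grid@spacing)
  new("RegistrationResult", translation = t, score = as.numeric(best))
}

#' Translate a binary mask on its own grid
#'
#' Occupancy is shifted by `t` voxels; voxels shifted outside the grid are
#' dropped (no wrap-around).
#'
#' @param mask a [BinaryMask].
#' @param t integer(3) voxel translation.
#' @return a [BinaryMask] on the same grid.
#' @export
applyTranslation <- function(mask, t) {
  t <- as.integer(round(t))
  if (all(t == 0L)) return(mask)
  sh <- mask@grid@shape
  out <- array(FALSE, sh)
  dstLo <- pmax(1L, 1L + t); dstHi <- pmin(sh, sh + t)
  if (all(dstLo <= dstHi)) {
    srcLo <- dstLo - t; srcHi <- dstHi - t
    out[dstLo[1L]:dstHi[1L], dstLo[2L]:dstHi[2L], dstLo[3L]:dstHi[3L]] <-
      mask@values[srcLo[1L]:srcHi[1L], srcLo[2L]:srcHi[2L],
                  srcLo[3L]:srcHi[3L]]
  }
  binaryMask(out, mask@grid)
}

#' Look up the overlap score of one translation in a ScoreVolume
#' @param sv a [ScoreVolume].
#' @param t integer(3) translation.
#' @return numeric overlap count (0 when `t` is outside the stored range).
#' @export
scoreAt <- function(sv, t) {
  i <- match(t[1L], sv@uOffsets)
  j <- match(t[2L], sv@vOffsets)
  k <- match(t[3L], sv@wOffsets)
  if (anyNA(c(i, j, k))) return(0)
  sv@scores[i, j, k]
}

#' @describeIn translation translation of a RegistrationResult
#' @export
setMethod("translation", "RegistrationResult", function(x) x@translation)
#' @describeIn regScore score of a RegistrationResult
#' @export
setMethod("regScore", "RegistrationResult", function(x) x@score)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: translation (%d, %d, %d) voxels, overlap %g\n",
              object@translation[1L], object@translation[2L],
              object@translation[3L], object@score))
})

setMethod("show", "ScoreVolume", function(object) {
  cat(sprintf("ScoreVolume: %d x %d x %d candidate translations, max overlap %g\n",
              dim(object@scores)[1L], dim(object@scores)[2L],
              dim(object@scores)[3L], max(object@scores)))
})
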