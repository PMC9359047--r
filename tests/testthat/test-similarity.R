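test_that("dice reproduces hand-computed overlaps and edge cases", {
  g <- makeGrid(c(12L, 12L, 12L), 2)
  a <- blockMask(g, c(2, 6), c(2, 6), c(2, 5))       # 5*5*4 = 100 voxels
  b <- blockMask(g, c(3, 6), c(3, 7), c(3, 5))       # 4*5*3 = 60 voxels
  # overlap: x 3..6, y 3..6, z 3..5 -> 4*4*3 = wait, construct |a^b| = 40
  expect_equal(voxelCount(a), 100L)
  expect_equal(voxelCount(b), 60L)
  inter <- sum(maskValues(a) & maskValues(b))
  expect_equal(dice(a, b), 2 * inter / 160)

  # the canonical |a|=100, |b|=60, |a^b|=40 case gives exactly 0.5
  b3v <- array(FALSE, c(12L, 12L, 12L))
  b3v[3:6, 2:6, 3:4] <- TRUE                          # 40 voxels, all inside a
  b3v[8:11, 8:12, 7] <- TRUE                          # 20 voxels, outside a
  b3 <- binaryMask(b3v, g)
  expect_equal(voxelCount(b3), 60L)
  expect_equal(sum(maskValues(a) & maskValues(b3)), 40L)
  expect_equal(dice(a, b3), 0.5)

  expect_equal(dice(a, a), 1)
  disj <- blockMask(g, c(8, 11), c(8, 11), c(8, 11))
  expect_equal(dice(a, disj), 0)
  expect_error(dice(emptyMask(g), emptyMask(g)), "undefined")
})

test_that("dice is symmetric and invariant under a common translation", {
  set.seed(9)
  g <- makeGrid(c(14L, 14L, 14L), 2)
  for (rep in 1:6) {
    core <- array(FALSE, c(14L, 14L, 14L))
    core[5:9, 5:9, 5:9] <- stats::runif(125) < 0.5
    core2 <- array(FALSE, c(14L, 14L, 14L))
    core2[5:9, 5:9, 5:9] <- stats::runif(125) < 0.5
    if (sum(core) + sum(core2) == 0) next
    a <- binaryMask(core, g); b <- binaryMask(core2, g)
    expect_equal(dice(a, b), dice(b, a))
    t <- sample(-3:3, 3, replace = TRUE)
    expect_equal(dice(applyTranslation(a, t), applyTranslation(b, t)),
                 dice(a, b))
  }
})

test_that("scorePair undoes rigid shifts and scores independent displacements", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  test <- blockPatient("T", g)
  # exact copy: perfect match at zero translation
  s <- scorePair(test, blockPatient("C", g))
  expect_identical(translation(s), c(0L, 0L, 0L))
  expect_equal(unname(s@dsc), c(1, 1, 1))

  # whole-patient rigid shift is fully undone
  s <- scorePair(test, blockPatient("C", g, ptvShift = c(3, 2, 1),
                                    bladderShift = c(3, 2, 1),
                                    rectumShift = c(3, 2, 1)))
  expect_identical(translation(s), c(-3L, -2L, -1L))
  expect_equal(unname(s@dsc), c(1, 1, 1))

  # only the bladder displaced: PTV and rectum still perfect, bladder DSC
  # equals the voxel-count formula on the displaced overlap
  cand <- blockPatient("C", g, bladderShift = c(2, 0, 0))
  s <- scorePair(test, cand)
  expect_equal(s@dsc[["PTV"]], 1)
  expect_equal(s@dsc[["rectum"]], 1)
  bt <- maskValues(getStructure(test, "bladder"))
  bc <- maskValues(getStructure(cand, "bladder"))
  expect_equal(s@dsc[["bladder"]],
               2 * sum(bt & bc) / (sum(bt) + sum(bc)))
  expect_lt(s@dsc[["bladder"]], 1)
})

# a small database with controlled, distinct rankings
.makeRankDB <- function(g, n = 6) {
  lapply(seq_len(n), function(i)
    blockPatient(sprintf("DB%02d", i), g,
                 ptvShift = c(0, 0, 0),
                 bladderShift = c(i - 1, 0, 0),
                 rectumShift = c(0, 0, n - i),
                 achieved = rbind(achievedRow("rectum", 20 + i),
                                  achievedRow("bladder", 40 - i))))
}

test_that("matchPatient reproduces a brute-force sort of the score table", {
  g <- makeGrid(c("x" = 26L, 26L, 26L), 2.5)
  test <- blockPatient("T", g)
  db <- .makeRankDB(g, 6)
  sel <- matchPatient(test, db, kPtv = 4L, kOar = 2L)

  # brute-force oracle: score every candidate, sort by DSC then ID
  recs <- lapply(db, function(cand) scorePair(test, cand))
  ids <- vapply(recs, function(r) r@patientID, character(1))
  dsc <- function(nm) vapply(recs, function(r) r@dsc[[nm]], numeric(1))
  ptvOrder <- ids[order(-dsc("PTV"), ids)]
  expect_identical(sel@ptvTop, ptvOrder[1:4])
  inTop <- ids %in% sel@ptvTop
  rOrder <- ids[inTop][order(-dsc("rectum")[inTop], ids[inTop])]
  bOrder <- ids[inTop][order(-dsc("bladder")[inTop], ids[inTop])]
  expect_identical(sel@rectumTop, rOrder[1:2])
  expect_identical(sel@bladderTop, bOrder[1:2])
  # rectum and bladder rankings genuinely differ in this construction
  expect_false(identical(sel@rectumTop, sel@bladderTop))
  # constraints are the minima over the matched patients
  avals <- function(top, organ) vapply(top, function(id)
    achievedDVH(db[[match(id, ids)]])$value[
      achievedDVH(db[[match(id, ids)]])$structure == organ], numeric(1))
  expect_equal(constraints(sel)[["rectum"]], min(avals(sel@rectumTop, "rectum")))
  expect_equal(constraints(sel)[["bladder"]], min(avals(sel@bladderTop, "bladder")))
})

test_that("an exact copy of the test patient dominates every ranking", {
  g <- makeGrid(c(26L, 26L, 26L), 2.5)
  test <- blockPatient("T", g)
  db <- .makeRankDB(g, 4)
  db[[5]] <- blockPatient("COPY", g,
                          achieved = rbind(achievedRow("rectum", 33),
                                           achievedRow("bladder", 44)))
  sel <- matchPatient(test, db, kPtv = 3L, kOar = 1L)
  expect_identical(sel@ptvTop[1], "COPY")
  expect_identical(sel@rectumTop, "COPY")
  expect_identical(sel@bladderTop, "COPY")
  tab <- scoreTable(sel)
  row <- tab[tab$patient_id == "COPY", ]
  expect_equal(c(row$dsc_ptv, row$dsc_rectum, row$dsc_bladder), c(1, 1, 1))
})

test_that("identical candidates fall back to ID-order tie-breaks", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  test <- blockPatient("T", g)
  db <- lapply(c("B", "A", "D", "C"), function(id) blockPatient(id, g))
  sel <- matchPatient(test, db, kPtv = 3L, kOar = 2L)
  expect_identical(sel@ptvTop, c("A", "B", "C"))
  expect_identical(sel@rectumTop, c("A", "B"))
  expect_identical(sel@bladderTop, c("A", "B"))
})

test_that("leave-one-out excludes the test ID; small databases error", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  test <- blockPatient("T", g)
  db <- c(list(blockPatient("T", g)), .makeRankDB(g, 3))
  sel <- matchPatient(test, db, kPtv = 3L, kOar = 1L)
  expect_false("T" %in% scoreTable(sel)$patient_id)
  expect_error(matchPatient(test, db, kPtv = 4L), "lower kPtv")
  expect_error(matchPatient(test, db, kPtv = 2L, kOar = 3L), "kPtv >= kOar")
})

test_that("deriveConstraints takes the minimum and keeps the template intact", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  test <- blockPatient("T", g)
  db <- lapply(1:3, function(i)
    blockPatient(c("A", "B", "C")[i], g,
                 achieved = rbind(achievedRow("rectum", c(30.0, 25.5, 41.2)[i]),
                                  achievedRow("bladder", 35))))
  sel <- matchPatient(test, db, kPtv = 3L, kOar = 3L)
  obj <- deriveConstraints(sel, db)
  expect_equal(obj$value[obj$structure == "rectum"], 25.5)
  expect_equal(obj$metric[obj$structure == "rectum"], "V50Gy")
  expect_equal(obj$value[obj$structure == "bladder"], 35)   # all equal -> v

  # row-by-row: only the rectum/bladder volume rows differ from the template
  tpl <- objectiveTemplate()
  expect_identical(dim(obj), dim(tpl))
  changed <- obj$structure %in% c("rectum", "bladder")
  expect_identical(obj[!changed, ], tpl[!changed, ])
  expect_identical(tpl$metric[changed], c("V45Gy", "V45Gy"))
  expect_identical(tpl$value[changed], c(45, 45))

  # a matched patient without an achieved value is a named error
  db2 <- db
  db2[[2]]@achievedDVH <- achievedRow("bladder", 35)
  sel2 <- matchPatient(test, db2, kPtv = 3L, kOar = 3L)
  expect_error(deriveConstraints(sel2, db2), "B.*rectum|rectum.*B")
})

test_that("adding a lower achieved value can only lower the derived constraint", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  test <- blockPatient("T", g)
  db <- lapply(1:3, function(i)
    blockPatient(sprintf("P%d", i), g,
                 achieved = rbind(achievedRow("rectum", 30 + i),
                                  achievedRow("bladder", 40 + i))))
  base <- constraints(matchPatient(test, db, kPtv = 3L, kOar = 3L))
  # a new exact-copy patient with a lower rectum value enters every top list
  db2 <- c(db, list(blockPatient("P0", g,
                                 achieved = rbind(achievedRow("rectum", 12),
                                                  achievedRow("bladder", 55)))))
  more <- constraints(matchPatient(test, db2, kPtv = 4L, kOar = 4L))
  expect_lte(more[["rectum"]], base[["rectum"]])
  expect_equal(more[["rectum"]], 12)
  # the bladder constraint cannot rise either (min over a superset)
  expect_lte(more[["bladder"]], base[["bladder"]])
})
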