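test_that("axis-aligned squares rasterize to exact voxel counts", {
  g <- makeGrid(c(16L, 16L, 4L), 2)
  z0 <- origin(g)[3]
  sq <- function(z, half = 5)
    list(z = z, x = c(-half, half, half, -half), y = c(-half, -half, half, half))
  # 10 mm x 10 mm square on a 2 mm grid: 5 x 5 voxel centers inside
  m1 <- rasterizePolygonStack(list(sq(z0)), g)
  expect_equal(voxelCount(m1), 25L)
  # same square repeated on 3 slices
  m3 <- rasterizePolygonStack(lapply(0:2, function(k) sq(z0 + k * 2)), g)
  expect_equal(voxelCount(m3), 75L)
  # empty contour list
  expect_equal(voxelCount(rasterizePolygonStack(list(), g)), 0L)
})

test_that("same-slice polygons XOR-combine (outer square minus hole)", {
  g <- makeGrid(c(24L, 24L, 3L), 2)
  z0 <- origin(g)[3]
  outer <- list(z = z0, x = c(-11, 11, 11, -11), y = c(-11, -11, 11, 11))
  inner <- list(z = z0, x = c(-5, 5, 5, -5), y = c(-5, -5, 5, 5))
  ring <- rasterizePolygonStack(list(outer, inner), g)
  no <- rasterOracleCount(g, outer$x, outer$y)
  ni <- rasterOracleCount(g, inner$x, inner$y)
  expect_equal(voxelCount(ring), no - ni)
  # brute-force oracle agrees voxel-by-voxel on the ring slice
  cx <- origin(g)[1] + (seq_len(24) - 1) * 2
  cy <- origin(g)[2] + (seq_len(24) - 1) * 2
  for (i in c(1, 6, 12, 18)) for (j in c(1, 6, 12, 18)) {
    want <- xor(pipOracle(cx[i], cy[j], outer$x, outer$y),
                pipOracle(cx[i], cy[j], inner$x, inner$y))
    expect_identical(maskValues(ring)[i, j, 1], want)
  }
})

test_that("rasterization matches the even-odd oracle on random simple polygons", {
  set.seed(42)
  g <- makeGrid(c(20L, 20L, 1L), 2.5)
  z0 <- origin(g)[3]
  for (rep in 1:8) {
    nv <- sample(3:12, 1)
    # star-shaped polygon around a random center: simple by construction
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(nv, 4, 22)
    cx0 <- stats::runif(1, -5, 5); cy0 <- stats::runif(1, -5, 5)
    vx <- cx0 + rad * cos(ang); vy <- cy0 + rad * sin(ang)
    m <- rasterizePolygonStack(list(list(z = z0, x = vx, y = vy)), g)
    expect_equal(voxelCount(m), rasterOracleCount(g, vx, vy),
                 info = paste("polygon rep", rep))
  }
})

test_that("contours off the grid extent are skipped with a warning", {
  g <- makeGrid(c(8L, 8L, 4L), 2)
  far <- list(z = origin(g)[3] + 100, x = c(-5, 5, 5, -5),
              y = c(-5, -5, 5, 5))
  expect_warning(m <- rasterizePolygonStack(list(far), g), "skipped")
  expect_equal(voxelCount(m), 0L)
})

test_that("mask resampling is identity on the same grid and recovers round trips", {
  g <- makeGrid(c(16L, 16L, 16L), 2)
  set.seed(7)
  m <- randomMask(c(16L, 16L, 16L), 0.3, spacing = 2)
  expect_identical(maskValues(resampleMask(m, g)), maskValues(m))

  # refine 2x then return: original recovered exactly (nearest neighbor)
  fine <- makeGrid(c(32L, 32L, 32L), 1, origin = origin(g) - 0.5)
  back <- resampleMask(resampleMask(m, fine), voxelGrid(m))
  expect_identical(maskValues(back), maskValues(m))

  # single voxel at the origin survives a spacing-doubled resample
  g1 <- makeGrid(c(9L, 9L, 9L), 2, origin = c(0, 0, 0))
  v <- array(FALSE, c(9L, 9L, 9L)); v[1, 1, 1] <- TRUE
  coarse <- makeGrid(c(5L, 5L, 5L), 4, origin = c(0, 0, 0))
  r <- resampleMask(binaryMask(v, g1), coarse)
  expect_equal(voxelCount(r), 1L)
  expect_true(maskValues(r)[1, 1, 1])
})

test_that("resampling a convex mask to a 2x finer grid preserves volume within 5%", {
  g <- makeGrid(c(24L, 24L, 24L), 3)
  ball <- local({   # 24 mm radius sphere
    co <- expand.grid(x = origin(g)[1] + (0:23) * 3,
                      y = origin(g)[2] + (0:23) * 3,
                      z = origin(g)[3] + (0:23) * 3)
    array(co$x^2 + co$y^2 + co$z^2 <= 24^2, c(24, 24, 24))
  })
  m <- binaryMask(ball, g)
  fine <- makeGrid(c(48L, 48L, 48L), 1.5, origin = origin(g) - 0.75)
  mf <- resampleMask(m, fine)
  expect_lt(abs(structureVolume(mf) - structureVolume(m)) /
            structureVolume(m), 0.05)
})

test_that("contour files read with alias mapping; PTV is mandatory", {
  g <- makeGrid(c(16L, 16L, 4L), 2)
  z0 <- origin(g)[3]
  sq <- function() list(z = z0, x = c(-5, 5, 5, -5), y = c(-5, -5, 5, 5))
  doc <- list(patient_id = "P1", rois = list(
    list(name = "PTV", contours = list(sq())),
    list(name = "Bladder_full", contours = list(sq())),
    list(name = "WeirdRing", contours = list(sq()))))
  f <- withr::local_tempfile(fileext = ".contours.json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_warning(st <- readContourSet(f, g), "WeirdRing")
  expect_setequal(structureNames(st), c("PTV", "bladder"))
  expect_equal(voxelCount(getStructure(st, "bladder")), 25L)

  doc$rois <- doc$rois[-1]   # drop the PTV
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(readContourSet(f, g)), "PTV")

  writeLines("{ not json", f)
  expect_error(readContourSet(f, g), "malformed")
})

test_that("dose files apply scaling, reject missing scaling, resample linearly", {
  g <- makeGrid(c(8L, 6L, 4L), 2, origin = c(0, 0, 0))
  f <- withr::local_tempfile(fileext = ".dose.json")
  doc <- list(shape = gridShape(g), spacing = spacing(g), origin = origin(g),
              scaling = 0.01, values = rep(4213, prod(gridShape(g))))
  jsonlite::write_json(doc, f, digits = NA)
  d <- readDoseGrid(f)
  expect_equal(unique(as.vector(doseValues(d))), 42.13)

  doc$scaling <- NULL
  jsonlite::write_json(doc, f, digits = NA)
  expect_error(readDoseGrid(f), "scaling")

  # linear ramp along x resamples to the analytic line at every voxel center
  ramp <- array(rep((0:7) * 2.0, times = 6 * 4), c(8, 6, 4))  # dose = x mm
  doc <- list(shape = gridShape(g), spacing = spacing(g), origin = origin(g),
              scaling = 0.1, values = as.vector(ramp) * 10)
  jsonlite::write_json(doc, f, digits = NA)
  target <- makeGrid(c(15L, 6L, 4L), c(1, 2, 2), origin = c(0, 0, 0))
  dr <- readDoseGrid(f, target)
  xs <- (0:14) * 1.0
  expect_equal(doseValues(dr)[, 3, 2], xs, tolerance = 1e-12)
})

test_that("patient records round-trip through the mask bundle format", {
  g <- makeGrid(c(24L, 24L, 24L), 2.5)
  rec <- blockPatient("RT01", g,
                      achieved = rbind(achievedRow("rectum", 31.25),
                                       achievedRow("bladder", 12.5)))
  f <- withr::local_tempfile(fileext = ".masks.json")
  writePatientRecord(rec, f)
  back <- readPatientRecord(f)
  expect_equal(patientID(back), "RT01")
  expect_setequal(structureNames(back), structureNames(rec))
  for (nm in structureNames(rec))
    expect_identical(maskValues(getStructure(back, nm)),
                     maskValues(getStructure(rec, nm)))
  expect_equal(achievedDVH(back)$value, c(31.25, 12.5))
  expect_true(sameGrid(voxelGrid(back@structures), g))
})

test_that("structure sets enforce one shared grid and canonical names", {
  g1 <- makeGrid(c(8L, 8L, 8L), 2)
  g2 <- makeGrid(c(8L, 8L, 8L), 3)
  a <- blockMask(g1, c(2, 4), c(2, 4), c(2, 4))
  b <- blockMask(g2, c(2, 4), c(2, 4), c(2, 4))
  expect_error(structureSet("X", list(PTV = a, rectum = b)), "share")
  expect_error(structureSet("X", list(rectum = a)), "PTV")
  expect_error(structureSet("X", list(PTV = a, tumour_bed = a)),
               "non-canonical")
})
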