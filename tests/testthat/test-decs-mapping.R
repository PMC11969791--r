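mapStudy <- function(truth = isoParams(k = 0.008, alpha = 0.18))
  makeAnimal(truth, grid = Grid3D(16, 0.5), times = c(0, 15, 30, 60, 120),
             noise = NoiseModel("none"))

centralSlab <- function(grid, halfWidth = 1L) {
  d <- grid@shape
  mid <- (d[3] + 1L) %/% 2L
  v <- array(FALSE, d)
  v[, , (mid - halfWidth):(mid + halfWidth)] <- TRUE
  v
}

test_that("local D map is flat on a homogeneous study and masked outside", {
  st <- mapStudy()
  pm <- computeLocalDMap(st, windowRadius = 1L, k = 0.008,
                         voxels = centralSlab(studyGrid(st)))
  v <- fieldValues(pm)
  inside <- v[!is.na(v)]
  expect_gt(length(inside), 100)
  ## unbiased and nearly constant at the true D
  expect_lt(abs(median(inside) - 0.02) / 0.02, 0.02)
  expect_lt(sd(inside) / mean(inside), 0.05)
  ## voxels outside the requested slab stay masked
  expect_true(all(is.na(v[, , 1:5])))
  expect_error(computeLocalDMap(st, windowRadius = 0L), "3 voxels")
  expect_error(
    computeLocalDMap(makeAnimal(isoParams(), grid = Grid3D(12, 0.5),
                                times = c(0, 30, 60),
                                noise = NoiseModel("none"))),
    "3 post-injection")
})

test_that("preset maps order as the group presets do", {
  slab <- centralSlab(Grid3D(16, 0.5))
  stS <- mapStudy(shamTruth())
  stP <- mapStudy(pdTruth())
  pmS <- computeLocalDMap(stS, 1L, k = shamTruth()@k, voxels = slab)
  pmP <- computeLocalDMap(stP, 1L, k = pdTruth()@k, voxels = slab)
  mS <- median(fieldValues(pmS), na.rm = TRUE)
  mP <- median(fieldValues(pmP), na.rm = TRUE)
  expect_gt(mP, mS)   # PD-like preset has the larger diffusion coefficient
})

test_that("renders are deterministic and respect the color convention", {
  st <- mapStudy()
  pm <- computeLocalDMap(st, 1L, k = 0.008,
                         voxels = centralSlab(studyGrid(st), 0L))
  d1 <- file.path(tempdir(), "r1.png")
  d2 <- file.path(tempdir(), "r2.png")
  renderContour2D(pm, d1)
  renderContour2D(pm, d2)
  expect_true(file.exists(d1))
  expect_identical(unname(tools::md5sum(d1)), unname(tools::md5sum(d2)))
  w1 <- file.path(tempdir(), "w1.png")
  w2 <- file.path(tempdir(), "w2.png")
  renderWireframe3D(pm, w1)
  renderWireframe3D(pm, w2)
  expect_identical(unname(tools::md5sum(w1)), unname(tools::md5sum(w2)))
})

test_that("degenerate rendering inputs are handled", {
  g <- Grid3D(8, 0.5)
  ## constant map renders as a single-color fill without error
  flat <- new("ParamMap", values = array(0.02, g@shape), grid = g,
              units = "mm^2/min")
  f <- file.path(tempdir(), "flat.png")
  renderContour2D(flat, f)
  expect_true(file.exists(f))
  fw <- file.path(tempdir(), "flatw.png")
  renderWireframe3D(flat, fw)
  expect_true(file.exists(fw))
  ## fully masked slice is an error
  masked <- new("ParamMap", values = array(NA_real_, g@shape), grid = g,
                units = "mm^2/min")
  expect_error(renderContour2D(masked, tempfile()), "masked")
  expect_error(renderWireframe3D(masked, tempfile()), "masked")
  ## mismatched underlay is an error
  vals <- array(0.02, g@shape); vals[1, 1, 1] <- 0.03
  pm <- new("ParamMap", values = vals, grid = g, units = "mm^2/min")
  expect_error(renderContour2D(pm, tempfile(),
                               underlay = matrix(0, 4, 4)),
               "underlay")
  ## increasing contour levels are enforced
  expect_error(RenderConfig(levels = c(2, 1)), "increasing")
})

test_that("wireframe peak location matches the slice argmax", {
  g <- Grid3D(8, 0.5)
  vals <- array(0.01, g@shape)
  vals[3, 6, 4] <- 0.05
  pm <- new("ParamMap", values = vals, grid = g, units = "mm^2/min")
  sl <- fieldValues(pm)[, , 4]
  expect_equal(which(sl == max(sl), arr.ind = TRUE)[1, ], c(row = 3, col = 6))
  f <- file.path(tempdir(), "peak.png")
  renderWireframe3D(pm, f, slice = 4)
  expect_true(file.exists(f))
})
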