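test_that("ROI timecourses average baseline-subtracted signal correctly", {
  st <- noiselessStudy()
  g <- studyGrid(st)
  ## single-voxel mask returns that voxel's series
  m1 <- array(FALSE, g@shape); m1[12, 12, 12] <- TRUE
  tc1 <- extractTimecourse(st, m1)
  expect_equal(tc1@enhancement,
               fieldValues(st)[12, 12, 12, ] - fieldValues(st)[12, 12, 12, 1])
  ## whole-grid mean is proportional to the spatial mean concentration
  tc <- extractTimecourse(st)
  expect_equal(tc@enhancement[-1],
               apply(fieldValues(st)[, , , -1], 4, mean), tolerance = 1e-12)
  ## two disjoint masks combine by voxel count
  mA <- array(FALSE, g@shape); mA[1:10, , ] <- TRUE
  mB <- array(FALSE, g@shape); mB[11:24, , ] <- TRUE
  tcA <- extractTimecourse(st, mA); tcB <- extractTimecourse(st, mB)
  tcU <- extractTimecourse(st, mA | mB)
  nA <- sum(mA); nB <- sum(mB)
  expect_equal((nA * tcA@enhancement + nB * tcB@enhancement) / (nA + nB),
               tcU@enhancement, tolerance = 1e-12)
  expect_error(extractTimecourse(st, array(FALSE, g@shape)), "empty")
  expect_error(extractTimecourse(st, array(TRUE, c(2, 2, 2))), "dimensions")
})

test_that("half-life of a pure exponential is ln2 / rate", {
  t <- seq(0, 240, by = 15)
  tc <- ROITimecourse(t, exp(-log(2) / 70.33 * t))
  hl <- computeHalfLife(tc)
  expect_false(hl$censored)
  expect_equal(hl$Thalf, 70.33, tolerance = 1e-10)
  ## scale invariance
  hl2 <- computeHalfLife(ROITimecourse(t, 7 * exp(-log(2) / 70.33 * t)))
  expect_equal(hl2$Thalf, hl$Thalf)
  ## monotone increasing curve is right-censored
  hl3 <- computeHalfLife(ROITimecourse(t, t + 1))
  expect_true(hl3$censored)
  ## decline that never reaches half is right-censored with a lower bound
  hl4 <- computeHalfLife(ROITimecourse(t, exp(-1e-4 * t)))
  expect_true(hl4$censored)
  expect_equal(hl4$Thalf, 240)
})

test_that("D* is the geometric mean and alpha the amplitude inverse", {
  expect_equal(computeDstar(2, 2, 2), 2)
  expect_equal(computeDstar(1, 2, 4), 2)
  expect_equal(computeDstar(4, 1, 2), computeDstar(1, 2, 4))
  expect_error(computeDstar(-1, 2, 2), "> 0")
  expect_equal(deriveAlpha(A = 20, Q = 20)$alphaPct, 100)
  expect_equal(deriveAlpha(A = 20 / 0.18, Q = 20)$alphaPct, 18,
               tolerance = 1e-12)
  ## halving Q at fixed amplitude halves alpha
  expect_equal(deriveAlpha(A = 200, Q = 10)$alphaPct,
               deriveAlpha(A = 200, Q = 20)$alphaPct / 2)
  clip <- deriveAlpha(A = 10, Q = 20)
  expect_true(clip$clipped)
  expect_equal(clip$alphaPct, 100)
  expect_error(deriveAlpha(A = -1, Q = 20), "positive")
})

test_that("moment initialization recovers D and k from analytic snapshots", {
  p <- DiffusionParams(0.03, 0.015, 0.02, k = 0.009, alpha = 0.2)
  f <- evaluateField(p, SourceBolus(20), Grid3D(48, 0.5),
                     c(15, 30, 60, 90, 120))
  mi <- momentsInit(f)
  expect_lt(abs(mi$D[1] - 0.03) / 0.03, 0.05)
  expect_lt(abs(mi$D[2] - 0.015) / 0.015, 0.05)
  expect_lt(abs(mi$D[3] - 0.02) / 0.02, 0.05)
  expect_lt(abs(mi$k - 0.009) / 0.009, 0.05)
  ## per-axis inits ordered as the true coefficients
  expect_true(mi$D[2] < mi$D[3] && mi$D[3] < mi$D[1])
  ## k = 0 data give initial k ~ 0
  f0 <- evaluateField(DiffusionParams(0.02, k = 0, alpha = 0.2),
                      SourceBolus(20), Grid3D(48, 0.5), c(15, 60, 120))
  expect_lt(momentsInit(f0)$k, 1e-5)
  expect_error(momentsInit(f0@values[, , , 1, drop = FALSE],
                           Grid3D(48, 0.5), 15), "two snapshots")
})

test_that("noiseless fits recover all parameters to < 1%", {
  truth <- DiffusionParams(0.02, k = 0.008, alpha = 0.18)
  st <- makeAnimal(truth, grid = Grid3D(32, 0.5), noise = NoiseModel("none"))
  res <- fitDiffusionModel(st)
  expect_true(res@converged)
  expect_lt(abs(res@Dstar - 0.02) / 0.02, 0.01)
  expect_lt(abs(res@k - 0.008) / 0.008, 0.01)
  expect_lt(abs(res@alphaPct - 18) / 18, 0.01)
  expect_gt(res@r2, 0.999)
})

test_that("anisotropic fit nests the isotropic model", {
  truth <- DiffusionParams(0.02, k = 0.005, alpha = 0.2)
  st <- makeAnimal(truth, grid = Grid3D(24, 0.5), noise = NoiseModel("none"))
  iso <- fitDiffusionModel(st, opts = FitOptions(isotropic = TRUE))
  ani <- fitDiffusionModel(st, opts = FitOptions(isotropic = FALSE))
  expect_equal(ani@Dx, ani@Dy, tolerance = 1e-3)
  expect_equal(ani@Dy, ani@Dz, tolerance = 1e-3)
  expect_equal(ani@Dstar, iso@Dstar, tolerance = 1e-3)
  ## truly anisotropic truth is resolved per axis
  tra <- DiffusionParams(0.03, 0.015, 0.02, k = 0.005, alpha = 0.2)
  sta <- makeAnimal(tra, grid = Grid3D(24, 0.5), noise = NoiseModel("none"))
  fa <- fitDiffusionModel(sta, opts = FitOptions(isotropic = FALSE))
  expect_lt(abs(fa@Dx - 0.03) / 0.03, 0.02)
  expect_lt(abs(fa@Dy - 0.015) / 0.015, 0.02)
})

test_that("degenerate inputs are rejected, not silently fitted", {
  st <- noiselessStudy()
  st@signal[] <- 0
  expect_error(fitDiffusionModel(st), "degenerate")
  st2 <- noiselessStudy(times = c(0, 30))
  expect_error(fitDiffusionModel(st2), "two post-injection")
})

test_that("estimates are invariant to global signal scaling", {
  truth <- DiffusionParams(0.02, k = 0.008, alpha = 0.18)
  st1 <- makeAnimal(truth, grid = Grid3D(24, 0.5),
                    signalParams = SignalParams(kappa = 1),
                    noise = NoiseModel("none"))
  st2 <- makeAnimal(truth, grid = Grid3D(24, 0.5),
                    signalParams = SignalParams(kappa = 2.5),
                    noise = NoiseModel("none"))
  r1 <- fitDiffusionModel(st1)
  r2 <- fitDiffusionModel(st2)
  expect_equal(r1@Dstar, r2@Dstar, tolerance = 1e-6)
  expect_equal(r1@k, r2@k, tolerance = 1e-4)
  expect_equal(r1@alphaPct, r2@alphaPct, tolerance = 1e-6)
  expect_equal(r1@Thalf, r2@Thalf, tolerance = 1e-6)
})

test_that("relaxivity-mode studies are fitted through the inverse map", {
  truth <- DiffusionParams(0.02, k = 0.008, alpha = 0.18)
  ## short-TR spoiled-gradient sequence: wide invertible enhancement range
  sp <- SignalParams("relaxivity", TR = 0.008, flipAngle = 15)
  st <- makeAnimal(truth, grid = Grid3D(24, 0.5), signalParams = sp,
                   noise = NoiseModel("none"))
  res <- fitDiffusionModel(st)
  expect_lt(abs(res@Dstar - 0.02) / 0.02, 0.01)
  expect_lt(abs(res@alphaPct - 18) / 18, 0.01)
})

test_that("bias increases as time points or informative voxels shrink", {
  ## seeded design sweep: median error with 3 post-injection times should
  ## not beat the full schedule
  truth <- shamTruth()
  errFor <- function(times) {
    es <- sapply(1:4, function(s) {
      st <- makeAnimal(truth, grid = Grid3D(32, 0.5), times = times,
                       noise = NoiseModel("rician", NA), peakSNR = 20,
                       seed = 400 + s)
      r <- fitDiffusionModel(st)
      abs(r@k - truth@k) / truth@k
    })
    median(es)
  }
  eFull <- errFor(defaultSchedule())
  eShort <- errFor(c(0, 15, 30, 60))
  expect_lte(eFull, eShort + 0.05)
})
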