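test_that("makeAnimal composes forward and signal models with ground truth", {
  truth <- isoParams(k = 0.008, alpha = 0.18)
  st <- noiselessStudy(truth)
  expect_s4_class(st, "TracerStudy")
  expect_identical(groundTruth(st), truth)
  ## noiseless signal equals kappa * concentration field voxelwise
  f <- evaluateField(truth, SourceBolus(20), studyGrid(st),
                     scanTimes(st)[-1])
  expect_equal(fieldValues(st)[, , , -1], fieldValues(f), tolerance = 1e-12)
  expect_true(all(fieldValues(st)[, , , 1] == 0))
  expect_error(makeAnimal(truth, times = c(15, 30)), "baseline")
})

test_that("same seed gives a bit-identical study; doubling Q doubles signal", {
  truth <- isoParams()
  a <- makeAnimal(truth, grid = smallGrid(16), times = shortSchedule(),
                  noise = NoiseModel("rician", NA), peakSNR = 20, seed = 3L)
  b <- makeAnimal(truth, grid = smallGrid(16), times = shortSchedule(),
                  noise = NoiseModel("rician", NA), peakSNR = 20, seed = 3L)
  expect_identical(fieldValues(a), fieldValues(b))
  p1 <- InjectionProtocol(volume = 2)
  p2 <- InjectionProtocol(volume = 4)
  s1 <- makeAnimal(truth, p1, smallGrid(16), shortSchedule(),
                   noise = NoiseModel("none"))
  s2 <- makeAnimal(truth, p2, smallGrid(16), shortSchedule(),
                   noise = NoiseModel("none"))
  expect_equal(fieldValues(s2), 2 * fieldValues(s1), tolerance = 1e-12)
})

test_that("default designs reproduce the reference table rows", {
  d <- defaultDesigns(groups = c("sham", "pd", "st"))
  expect_equal(unname(d$sham@mean["alpha"]), 17.10)
  expect_equal(unname(d$pd@mean["Dstar"]), 4.21)
  expect_equal(unname(d$sham@mean["Dstar"]), 3.09)
  expect_gt(d$pd@mean["Thalf"], d$sham@mean["Thalf"])   # 114.40 > 70.33
  expect_gt(d$pd@mean["Thalf"], d$st@mean["Thalf"])     # 114.40 > 96.47
  expect_equal(unname(d$sham@sd["kprime"]), 0.05)
})

test_that("sampled truths convert reporting-scale values to physical units", {
  d <- defaultDesigns(groups = "sham")$sham
  set.seed(1)
  tr <- sampleTruth(d)
  expect_equal(tr$params@Dx, reportedToInternalD(tr$Dstar))
  expect_equal(tr$params@k, log(2) / tr$Thalf)
  expect_equal(tr$params@alpha, tr$alpha / 100)
})

test_that("zero-SD designs give identical animals; cohorts are seeded", {
  d <- defaultDesigns(groups = "sham", n = 2L, grid = Grid3D(12, 0.5),
                      noiseKind = "none")$sham
  d@sd[] <- 0
  coh <- makeGroupDataset(list(d), seed = 7L)
  expect_identical(fieldValues(coh$studies[[1]]),
                   fieldValues(coh$studies[[2]]))
  coh2 <- makeGroupDataset(list(d), seed = 7L)
  expect_identical(fieldValues(coh$studies[[1]]),
                   fieldValues(coh2$studies[[1]]))
})

test_that("cohort sample means track the design means", {
  designs <- defaultDesigns(groups = c("sham", "pd"), n = 6L,
                            grid = Grid3D(8, 0.5), noiseKind = "none")
  coh <- makeGroupDataset(designs, seed = 11L)
  tr <- coh$truth
  for (g in c("sham", "pd")) {
    rows <- tr[tr$group == g, ]
    des <- designs[[g]]
    for (parm in c("Dstar", "Thalf", "alpha")) {
      tol <- 3 * des@sd[parm] / sqrt(6)
      expect_lt(abs(mean(rows[[parm]]) - des@mean[parm]), tol + 1e-12)
    }
  }
})

test_that("a noiseless study is a fixed point of the estimation pipeline", {
  truth <- DiffusionParams(reportedToInternalD(3.5), k = log(2) / 90,
                           alpha = 0.175)
  st <- makeAnimal(truth, grid = Grid3D(32, 0.5), noise = NoiseModel("none"))
  res <- fitDiffusionModel(st)
  expect_lt(abs(res@Dstar - truth@Dx) / truth@Dx, 0.01)
  expect_lt(abs(res@k - truth@k) / truth@k, 0.01)
  expect_lt(abs(res@alphaPct - 17.5) / 17.5, 0.01)
})
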