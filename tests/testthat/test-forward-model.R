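test_that("heat-kernel amplitude scales as t^(-3/2) at the source", {
  p <- DiffusionParams(0.03, k = 0, alpha = 0.2)
  b <- SourceBolus(20)
  for (t in c(10, 40, 123)) {
    c1 <- pointSourceConcentration(p, b, c(0, 0, 0), t)
    c2 <- pointSourceConcentration(p, b, c(0, 0, 0), 2 * t)
    expect_equal(c2 / c1, 2^(-3 / 2), tolerance = 1e-12)
  }
})

test_that("closed form is symmetric under simultaneous axis/coefficient swap", {
  p1 <- DiffusionParams(0.02, 0.05, 0.01, k = 0.003, alpha = 0.15)
  p2 <- DiffusionParams(0.05, 0.02, 0.01, k = 0.003, alpha = 0.15)
  b <- SourceBolus(20)
  loc <- c(1.2, -0.7, 0.4)
  locSwap <- c(-0.7, 1.2, 0.4)
  expect_equal(pointSourceConcentration(p1, b, loc, 60),
               pointSourceConcentration(p2, b, locSwap, 60),
               tolerance = 1e-12)
})

test_that("closed form agrees with an independent fine-grid FD oracle", {
  ## frozen scenario: D = 0.02 mm^2/min isotropic, k = 0.01/min,
  ## alpha = 0.2, Q = 20 nmol, r = 1 mm, t = 60 min
  p <- DiffusionParams(0.02, k = 0.01, alpha = 0.2)
  b <- SourceBolus(20)
  analytic <- pointSourceConcentration(p, b, c(1, 0, 0), 60)
  expect_equal(analytic, 0.7609544, tolerance = 1e-6)
  grid <- Grid3D(48, 0.25)
  fd <- solveFD(p, b, grid, 60)
  xs <- axisCoords(grid, 1)
  ix <- which.min(abs(xs - 1))
  ic <- which.min(abs(xs))
  fdVal <- fieldValues(fd)[ix, ic, ic, 1]
  ## compare at the voxel center nearest (1, 0, 0) mm
  ref <- pointSourceConcentration(p, b, c(xs[ix], xs[ic], xs[ic]), 60)
  expect_lt(abs(fdVal - ref) / ref, 0.02)
})

test_that("evaluateField matches pointSourceConcentration at voxel centers", {
  p <- DiffusionParams(0.02, 0.03, 0.01, k = 0.005, alpha = 0.2)
  b <- SourceBolus(20, position = c(0.25, 0, -0.25))
  g <- smallGrid(12)
  f <- evaluateField(p, b, g, c(30, 90))
  loc <- c(axisCoords(g, 1)[3], axisCoords(g, 2)[7], axisCoords(g, 3)[5])
  expect_equal(fieldValues(f)[3, 7, 5, 2],
               pointSourceConcentration(p, b, loc, 90), tolerance = 1e-12)
  ## single voxel, single time
  g1 <- Grid3D(c(3, 3, 3), 0.5)
  f1 <- evaluateField(p, b, g1, 45)
  expect_equal(fieldValues(f1)[2, 2, 2, 1],
               pointSourceConcentration(
                 p, b, c(axisCoords(g1, 1)[2], axisCoords(g1, 2)[2],
                         axisCoords(g1, 3)[2]), 45),
               tolerance = 1e-12)
})

test_that("clearance separates as an exact e^(-kt) factor", {
  b <- SourceBolus(20)
  g <- smallGrid(16)
  times <- c(30, 120)
  f0 <- evaluateField(DiffusionParams(0.02, k = 0, alpha = 0.2), b, g, times)
  f1 <- evaluateField(DiffusionParams(0.02, k = 0.012, alpha = 0.2), b, g,
                      times)
  for (j in seq_along(times))
    expect_equal(fieldValues(f1)[, , , j],
                 fieldValues(f0)[, , , j] * exp(-0.012 * times[j]),
                 tolerance = 1e-12)
})

test_that("field evaluation rejects empty times and pre-onset times are 0", {
  p <- isoParams()
  b <- SourceBolus(20, onset = 10)
  expect_error(evaluateField(p, b, smallGrid(), numeric(0)), "non-empty")
  expect_equal(pointSourceConcentration(p, b, c(1, 0, 0), c(5, 10)),
               c(0, 0))
  expect_error(pointSourceConcentration(p, SourceBolus(20), c(0, 0, 0), 0),
               "singular|non-empty|0")
})

test_that("total tracer amount follows Q e^(-kt) on a wide domain", {
  p <- DiffusionParams(0.02, k = 0.01, alpha = 0.2)
  b <- SourceBolus(20)
  g <- Grid3D(48, 0.5)                     # 24 mm >> 6 diffusion lengths early
  f <- evaluateField(p, b, g, c(10, log(2) / 0.01, 100))
  amt <- totalAmount(f, 0.2)
  expect_equal(amt$amount[1] / exp(-0.01 * 10), 20, tolerance = 5e-3)  # ~Q e^{-kt} at small t
  expect_equal(amt$amount[2] / 20, 0.5, tolerance = 5e-3)     # half at ln2/k
  expect_equal(amt$amount[3] / 20, exp(-1), tolerance = 5e-3) # e^-1 at t=1/k
  ## k = 0: conservation within discretization
  f0 <- evaluateField(DiffusionParams(0.02, k = 0, alpha = 0.2), b, g,
                      c(10, 60, 150))
  amt0 <- totalAmount(f0, 0.2)$amount
  expect_lt(max(abs(amt0 - 20)) / 20, 5e-3)
  expect_error(totalAmount(f, 1.2), "alpha")
})

test_that("finite-duration infusion conserves the injected amount", {
  p <- DiffusionParams(0.02, k = 0, alpha = 0.2)
  bInf <- SourceBolus(20, duration = 10)
  g <- Grid3D(48, 0.5)
  amt <- totalAmount(evaluateField(p, bInf, g, 60), 0.2)$amount
  expect_equal(amt, 20, tolerance = 1e-2)
  ## during infusion only part of Q is released; recently released tracer
  ## is narrower than a voxel, so the grid sum slightly undershoots
  bSlow <- SourceBolus(20, duration = 60)
  amtMid <- totalAmount(evaluateField(p, bSlow, g, 30), 0.2)$amount
  expect_equal(amtMid / 20, 0.5, tolerance = 0.08)
})

test_that("FD solver conserves mass with no-flux boundaries and k = 0", {
  p <- DiffusionParams(0.03, k = 0, alpha = 0.2)
  b <- SourceBolus(20)
  g <- smallGrid(20)
  f <- solveFD(p, b, g, c(60, 120), dt = 1)
  amt <- totalAmount(f, 0.2)$amount
  expect_equal(amt[1], amt[2], tolerance = 1e-10)
})

test_that("FD solver handles zero source and enforces explicit stability", {
  g <- smallGrid(12)
  f <- solveFD(isoParams(), NULL, g, c(10, 20))
  expect_true(all(fieldValues(f) == 0))
  expect_error(
    solveFD(isoParams(), SourceBolus(20), g, 120, method = "explicit",
            dt = 100),
    "stability")
  expect_error(
    solveFD(isoParams(D = 0.002), SourceBolus(20), smallGrid(16), 5),
    "warmup")
})

test_that("explicit and implicit schemes agree with the analytic solution", {
  p <- DiffusionParams(0.02, k = 0.01, alpha = 0.2)
  b <- SourceBolus(20)
  g <- Grid3D(32, 0.25)
  times <- c(20, 40)
  ana <- evaluateField(p, b, g, times)
  r2 <- gridR2(g)
  m <- r2 <= 4                          # within 2 mm of the source
  for (method in c("implicit", "explicit")) {
    fd <- solveFD(p, b, g, times, method = method)
    for (j in seq_along(times)) {
      a <- fieldValues(ana)[, , , j][m]
      v <- fieldValues(fd)[, , , j][m]
      expect_lt(max(abs(v - a) / a), 0.02)
    }
  }
})

test_that("anisotropic diffusion elongates the cloud as Var_x = 2 Var_y", {
  p <- DiffusionParams(0.04, 0.02, 0.02, k = 0, alpha = 0.2)
  b <- SourceBolus(20)
  g <- Grid3D(40, 0.4)
  fd <- solveFD(p, b, g, 120)
  v <- fieldValues(fd)[, , , 1]
  w <- v / sum(v)
  varAxis <- function(a) {
    marg <- apply(w, a, sum)
    x <- axisCoords(g, a)
    mu <- sum(x * marg)
    sum((x - mu)^2 * marg)
  }
  expect_equal(varAxis(1) / varAxis(2), 2, tolerance = 0.05)
  expect_equal(varAxis(2), varAxis(3), tolerance = 0.02)
})

test_that("analytic solution satisfies the discretized PDE at second order", {
  ## central-difference residual of the analytic solution must shrink ~h^2
  p <- DiffusionParams(0.02, k = 0.01, alpha = 0.2)
  b <- SourceBolus(20)
  resNorm <- function(h) {
    n <- round(8 / h)
    g <- Grid3D(n, h)
    t0 <- 60; dt <- 0.01
    f <- evaluateField(p, b, g, c(t0 - dt, t0, t0 + dt))
    v <- fieldValues(f)
    Ct <- (v[, , , 3] - v[, , , 1]) / (2 * dt)
    C <- v[, , , 2]
    lap <- array(0, dim(C))
    d <- dim(C)
    i <- 2:(d[1] - 1)
    lap[i, i, i] <-
      (C[i - 1, i, i] + C[i + 1, i, i] - 2 * C[i, i, i]) / h^2 * p@Dx +
      (C[i, i - 1, i] + C[i, i + 1, i] - 2 * C[i, i, i]) / h^2 * p@Dy +
      (C[i, i, i - 1] + C[i, i, i + 1] - 2 * C[i, i, i]) / h^2 * p@Dz
    r <- Ct[i, i, i] - (lap[i, i, i] - p@k * C[i, i, i])
    max(abs(r)) / max(C)
  }
  r1 <- resNorm(0.5)
  r2 <- resNorm(0.25)
  expect_gt(r1 / r2, 3)   # ~4 expected for a second-order stencil
})
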