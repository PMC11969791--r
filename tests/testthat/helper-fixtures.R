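## Shared fixtures: small, fast study configurations used across tests.

isoParams <- function(D = 0.02, k = 0.01, alpha = 0.2)
  DiffusionParams(D, k = k, alpha = alpha)

## sham-/PD-like physical truths derived from the reference table rows
shamTruth <- function()
  DiffusionParams(reportedToInternalD(3.09), k = log(2) / 70.33,
                  alpha = 0.1710)
pdTruth <- function()
  DiffusionParams(reportedToInternalD(4.21), k = log(2) / 114.40,
                  alpha = 0.1803)

smallGrid <- function(n = 24L, h = 0.5) Grid3D(n, h)

shortSchedule <- function() c(0, 15, 30, 60, 120)

noiselessStudy <- function(truth = isoParams(k = 0.008, alpha = 0.18),
                           grid = smallGrid(), times = shortSchedule())
  makeAnimal(truth, grid = grid, times = times,
             noise = NoiseModel("none"))

## squared distance from the grid center for masks
gridR2 <- function(grid, center = c(0, 0, 0)) {
  xs <- axisCoords(grid, 1) - center[1]
  ys <- axisCoords(grid, 2) - center[2]
  zs <- axisCoords(grid, 3) - center[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+")
}
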