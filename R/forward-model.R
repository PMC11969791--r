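#' @include AllClasses.R
NULL

#' Voxel-center coordinates of a grid axis
#'
#' @param grid a [Grid3D]
#' @param axis 1, 2 or 3
#' @return numeric vector of mm coordinates of voxel centers along the axis
#' @export
axisCoords <- function(grid, axis) {
  stopifnot(is(grid, "Grid3D"), axis %in% 1:3)
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1L) * grid@voxelSize[axis]
}

#' Voxel volume of a grid (mm^3)
#'
#' @param grid a [Grid3D]
#' @export
voxelVolume <- function(grid) prod(grid@voxelSize)

#' Convert diffusion coefficients between internal and reporting units
#'
#' Internally the package works in mm^2/min. Reported effective diffusion
#' coefficients for brain ECS tracers are conventionally displayed as
#' `scale` x mm^2/s (default scale 1e4, so an internal 0.0185 mm^2/min prints
#' as 3.09). The same display convention is applied to the clearance rate
#' when a reporting-scale k' is requested; the display scale is a labelling
#' convention, not a physical unit change.
#'
#' @param D diffusion coefficient(s) in mm^2/min
#' @param x diffusion coefficient(s) on the reporting scale
#' @param scale display scale factor relative to mm^2/s (default 1e4)
#' @return converted value(s)
#' @examples
#' internalToReportedD(0.01854)  # ~3.09
#' reportedToInternalD(3.09)
#' @export
internalToReportedD <- function(D, scale = 1e4) D / 60 * scale

#' @rdname internalToReportedD
#' @export
reportedToInternalD <- function(x, scale = 1e4) x * 60 / scale

## Free-space Green's function of the anisotropic diffusion-clearance
## equation dC/dt = Dx Cxx + Dy Cyy + Dz Czz - kC for a unit instantaneous
## point release at the origin at tau = 0:
##   G(r, tau) = exp(-sum ri^2/(4 Di tau) - k tau) / (8 (pi tau)^{3/2}
##               sqrt(Dx Dy Dz))
## integrates to exp(-k tau) over space. `dx2`, `dy2`, `dz2` are squared
## displacements; tau > 0.
.greenKernel <- function(dx2, dy2, dz2, tau, params) {
  amp <- exp(-params@k * tau) /
    (8 * (pi * tau)^1.5 * sqrt(params@Dx * params@Dy * params@Dz))
  amp * exp(-(dx2 / (4 * params@Dx * tau) +
              dy2 / (4 * params@Dy * tau) +
              dz2 / (4 * params@Dz * tau)))
}

#' Concentration from a point bolus (closed form)
#'
#' Evaluates the free-space solution of the anisotropic diffusion--clearance
#' equation for an injected point source: for an instantaneous bolus,
#' \deqn{C(r, t) = \frac{Q/\alpha}{8 (\pi \tau)^{3/2} \sqrt{D_x D_y D_z}}
#'   \exp\left(-\sum_i \frac{r_i^2}{4 D_i \tau} - k \tau\right),}
#' with \eqn{\tau = t - \mathrm{onset}}. The \eqn{Q/\alpha} scaling is the
#' source term of the ECS model: the tracer is restricted to the
#' extracellular fraction, so its concentration there exceeds the
#' tissue-average by \eqn{1/\alpha}. A finite infusion duration is handled by
#' time-convolution of the kernel with a constant release rate
#' (Gauss--Legendre quadrature).
#'
#' Times at or before the onset return 0. Evaluating exactly at the source
#' position at the instant of an instantaneous bolus is singular and raises
#' an error.
#'
#' @param params [DiffusionParams]
#' @param bolus [SourceBolus]
#' @param location numeric(3) mm, or an n x 3 matrix of locations
#' @param t time(s), min
#' @param quadNodes quadrature nodes for finite-duration infusion
#' @return concentration in mM; a vector over `t` (single location) or a
#'   matrix locations x times
#' @examples
#' p <- DiffusionParams(0.02, k = 0.01, alpha = 0.2)
#' b <- SourceBolus(20)
#' pointSourceConcentration(p, b, c(1, 0, 0), 60)
#' @export
pointSourceConcentration <- function(params, bolus, location, t,
                                     quadNodes = 24L) {
  stopifnot(is(params, "DiffusionParams"), is(bolus, "SourceBolus"))
  validObject(params); validObject(bolus)
  loc <- if (is.matrix(location)) location else matrix(location, ncol = 3L)
  stopifnot(ncol(loc) == 3L)
  t <- as.numeric(t)
  d <- sweep(loc, 2L, bolus@position)
  dx2 <- d[, 1L]^2; dy2 <- d[, 2L]^2; dz2 <- d[, 3L]^2
  r2 <- dx2 + dy2 + dz2
  out <- matrix(0, nrow(loc), length(t))
  for (j in seq_along(t)) {
    tau <- t[j] - bolus@onset
    if (tau == 0 && bolus@duration == 0 && any(r2 == 0))
      stop("singular evaluation: r = 0 at the instant of the bolus")
    if (tau <= 0) next
    if (bolus@duration == 0) {
      out[, j] <- (bolus@amount / params@alpha) *
        .greenKernel(dx2, dy2, dz2, tau, params)
    } else {
      ## constant release rate Q/duration over [onset, onset + duration]
      tEnd <- min(tau, bolus@duration)
      gl <- pracma::gaussLegendre(quadNodes, 0, tEnd)
      rate <- bolus@amount / bolus@duration / params@alpha
      acc <- numeric(nrow(loc))
      for (q in seq_along(gl$x)) {
        lag <- tau - gl$x[q]
        if (lag <= 0) next
        acc <- acc + gl$w[q] * .greenKernel(dx2, dy2, dz2, lag, params)
      }
      out[, j] <- rate * acc
    }
  }
  if (!is.matrix(location)) drop(out) else out
}

#' Sample the closed-form solution on a grid
#'
#' Evaluates [pointSourceConcentration()] at every voxel center of `grid` for
#' each requested time, exploiting the separability of the Gaussian kernel
#' along axes for an instantaneous bolus. Results agree with
#' [pointSourceConcentration()] at each voxel center to machine precision.
#'
#' @param params [DiffusionParams]
#' @param bolus [SourceBolus]
#' @param grid [Grid3D]
#' @param times scan times (min), non-empty
#' @return a [ConcentrationField]
#' @export
evaluateField <- function(params, bolus, grid, times) {
  stopifnot(is(params, "DiffusionParams"), is(bolus, "SourceBolus"),
            is(grid, "Grid3D"))
  validObject(params); validObject(grid)
  times <- as.numeric(times)
  if (!length(times)) stop("'times' must be non-empty")
  xs <- axisCoords(grid, 1L) - bolus@position[1L]
  ys <- axisCoords(grid, 2L) - bolus@position[2L]
  zs <- axisCoords(grid, 3L) - bolus@position[3L]
  vals <- array(0, c(grid@shape, length(times)))
  for (j in seq_along(times)) {
    tau <- times[j] - bolus@onset
    if (tau <= 0) next
    if (bolus@duration == 0) {
      amp <- (bolus@amount / params@alpha) * exp(-params@k * tau) /
        (8 * (pi * tau)^1.5 * sqrt(params@Dx * params@Dy * params@Dz))
      ax <- exp(-xs^2 / (4 * params@Dx * tau))
      ay <- exp(-ys^2 / (4 * params@Dy * tau))
      az <- exp(-zs^2 / (4 * params@Dz * tau))
      vals[, , , j] <- amp * (ax %o% ay %o% az)
    } else {
      tEnd <- min(tau, bolus@duration)
      gl <- pracma::gaussLegendre(24L, 0, tEnd)
      rate <- bolus@amount / bolus@duration / params@alpha
      acc <- array(0, grid@shape)
      for (q in seq_along(gl$x)) {
        lag <- tau - gl$x[q]
        if (lag <= 0) next
        amp <- exp(-params@k * lag) /
          (8 * (pi * lag)^1.5 * sqrt(params@Dx * params@Dy * params@Dz))
        ax <- exp(-xs^2 / (4 * params@Dx * lag))
        ay <- exp(-ys^2 / (4 * params@Dy * lag))
        az <- exp(-zs^2 / (4 * params@Dz * lag))
        acc <- acc + gl$w[q] * amp * (ax %o% ay %o% az)
      }
      vals[, , , j] <- rate * acc
    }
  }
  ConcentrationField(times, vals, grid)
}

#' Total tracer amount over time
#'
#' Integrates a concentration field to the tissue-level tracer amount,
#' \eqn{A(t) = \sum_v C_v(t)\, \alpha\, V_{voxel}} (nmol). For the free-space
#' analytic field on a domain spanning several diffusion lengths this equals
#' \eqn{Q e^{-kt}}: clearance is the only loss channel, so the amount decays
#' with first-order kinetics and halves every \eqn{\ln 2 / k} minutes.
#'
#' @param field a [ConcentrationField]
#' @param alpha ECS volume fraction in (0, 1]
#' @return data.frame with columns `time` (min) and `amount` (nmol)
#' @export
totalAmount <- function(field, alpha) {
  stopifnot(is(field, "ConcentrationField"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single number in (0, 1]")
  vv <- voxelVolume(field@grid)
  amt <- apply(field@values, 4L, sum) * alpha * vv
  data.frame(time = field@times, amount = amt)
}
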