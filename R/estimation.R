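#' @include AllClasses.R forward-model.R signal-model.R
NULL

#' Construct an ROI timecourse
#'
#' @param times scan times (min)
#' @param enhancement mean enhancement per time
#' @param nVoxels voxel count behind the mean
#' @param label ROI label
#' @return an [ROITimecourse]
#' @export
ROITimecourse <- function(times, enhancement, nVoxels = 1L,
                          label = "ROI") {
  new("ROITimecourse", times = as.numeric(times),
      enhancement = as.numeric(enhancement), nVoxels = as.integer(nVoxels),
      label = label)
}

#' Spherical ROI mask around a point
#'
#' The default analysis region: a sphere of radius `radius` mm around
#' `center` (by default the injection site at the grid center). A 4 mm
#' radius is large enough that diffusive escape from the ROI does not
#' dominate the clearance signal in the half-life, while remaining a local
#' region at the simulated rat-brain scale.
#'
#' @param grid [Grid3D]
#' @param center numeric(3) mm
#' @param radius mm
#' @return logical 3D array
#' @export
sphereROI <- function(grid, center = c(0, 0, 0), radius = 4) {
  stopifnot(is(grid, "Grid3D"), radius > 0)
  xs <- axisCoords(grid, 1L) - center[1L]
  ys <- axisCoords(grid, 2L) - center[2L]
  zs <- axisCoords(grid, 3L) - center[3L]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= radius^2
}

## Estimate the magnitude-image noise SD of a study. Prefers the recorded
## noise model; otherwise uses the baseline scan, whose signal is pure noise
## (Rayleigh for Rician data: median = sigma * sqrt(ln 4)).
.estimateNoiseSD <- function(study) {
  if (study@noise@kind == "none") return(0)
  if (!is.na(study@noise@sigma)) return(study@noise@sigma)
  stats::median(abs(study@signal[, , , 1L])) / sqrt(log(4))
}

## Rician first-moment bias correction: sqrt(max(S^2 - 2 sigma^2, 0)).
## E[S^2] = s^2 + 2 sigma^2 exactly for magnitude data, so the corrected
## value is a nearly unbiased amplitude estimate above ~1.5 sigma.
.ricianCorrect <- function(S, sigma) sqrt(pmax(S^2 - 2 * sigma^2, 0))

#' Extract the ROI mean-enhancement timecourse of a study
#'
#' Subtracts the pre-injection baseline scan voxelwise and averages over the
#' mask at every scan time (including the baseline itself, whose value is 0
#' up to noise). For Rician-noise studies the magnitude bias is removed
#' first (`biasCorrect = "auto"`): each voxel value is replaced by
#' \eqn{\sqrt{\max(S^2 - 2\hat\sigma^2, 0)}}, which is unbiased in the
#' second moment; without this, the noise floor of magnitude images inflates
#' low signals and distorts the decay of the curve.
#'
#' @param study [TracerStudy]
#' @param roi logical or 0/1 array matching the study grid, or NULL for the
#'   whole grid
#' @param biasCorrect `"auto"` (correct when the study's noise is Rician),
#'   `"always"` or `"never"`
#' @param label ROI label
#' @return an [ROITimecourse]
#' @export
extractTimecourse <- function(study, roi = NULL,
                              biasCorrect = c("auto", "always", "never"),
                              label = "ROI") {
  stopifnot(is(study, "TracerStudy"))
  biasCorrect <- match.arg(biasCorrect)
  validObject(study)
  d <- dim(study@signal)
  if (is.null(roi)) roi <- array(TRUE, d[1:3])
  if (!all(dim(roi) == d[1:3]))
    stop("ROI mask dimensions do not match the study grid")
  roi <- as.logical(roi)
  nv <- sum(roi)
  if (nv == 0L) stop("ROI mask is empty")
  sigma <- .estimateNoiseSD(study)
  correct <- switch(biasCorrect,
                    auto = study@noise@kind == "rician" && sigma > 0,
                    always = sigma > 0, never = FALSE)
  vol <- function(j) {
    v <- study@signal[, , , j][roi]
    if (correct) .ricianCorrect(v, sigma) else v
  }
  baseline <- vol(1L)
  enh <- vapply(seq_len(d[4L]), function(j) mean(vol(j) - baseline),
                numeric(1))
  ROITimecourse(study@times, enh, nv, label)
}

#' Half-life of an ROI enhancement curve
#'
#' The operational tracer half-life: the time elapsed from the global peak
#' of the enhancement curve to the first crossing of half the peak value,
#' located by log-linear interpolation between the bracketing samples (the
#' interpolation is exact for exponential decay). If the curve never falls
#' to half its peak within the schedule the result is right-censored and
#' `Thalf` is the lower bound; a monotone increasing curve is likewise
#' censored. When noise makes the half level be crossed several times, the
#' first crossing after the global peak is used.
#'
#' @param tc an [ROITimecourse]
#' @return list with `Thalf` (min), `censored` (logical), `peakTime` and
#'   `halfLevel`
#' @examples
#' t <- seq(0, 240, by = 15)
#' tc <- ROITimecourse(t, exp(-log(2) / 70.33 * t))
#' computeHalfLife(tc)$Thalf  # 70.33
#' @export
computeHalfLife <- function(tc) {
  stopifnot(is(tc, "ROITimecourse"))
  validObject(tc)
  y <- tc@enhancement
  t <- tc@times
  ip <- which.max(y)
  peak <- y[ip]
  if (peak <= 0) stop("enhancement curve has no positive peak")
  half <- peak / 2
  if (ip == length(y))  # still rising: the whole schedule is a lower bound
    return(list(Thalf = t[length(t)], censored = TRUE,
                peakTime = t[ip], halfLevel = half))
  below <- which(y[(ip + 1L):length(y)] <= half)
  if (!length(below))
    return(list(Thalf = t[length(t)] - t[ip], censored = TRUE,
                peakTime = t[ip], halfLevel = half))
  j <- ip + below[1L]               # first sample at/below half after peak
  y1 <- y[j - 1L]; y2 <- y[j]
  if (y2 == half || y1 <= half) {
    tc2 <- t[j]
  } else if (y2 > 0) {
    tc2 <- t[j - 1L] + (t[j] - t[j - 1L]) *
      (log(y1) - log(half)) / (log(y1) - log(y2))
  } else {                          # non-positive sample: linear fallback
    tc2 <- t[j - 1L] + (t[j] - t[j - 1L]) * (y1 - half) / (y1 - y2)
  }
  list(Thalf = tc2 - t[ip], censored = FALSE, peakTime = t[ip],
       halfLevel = half)
}

#' Scalar effective diffusion coefficient
#'
#' Combines per-axis diffusion coefficients into the single reported D* as
#' their geometric mean, \eqn{(D_x D_y D_z)^{1/3}} -- the isotropic
#' coefficient with the same Green's-function amplitude, and the identity on
#' isotropic input.
#'
#' @param Dx,Dy,Dz positive diffusion coefficients
#' @return D*, same units
#' @examples
#' computeDstar(1, 2, 4)  # 2
#' @export
computeDstar <- function(Dx, Dy = Dx, Dz = Dx) {
  if (any(c(Dx, Dy, Dz) <= 0)) stop("diffusion coefficients must be > 0")
  (Dx * Dy * Dz)^(1 / 3)
}

#' ECS volume fraction from the fitted source amplitude
#'
#' The volume fraction enters the tracer model through the source scaling
#' \eqn{Q/\alpha}: the fitted concentration-scale amplitude A estimates
#' \eqn{Q/\alpha}, so \eqn{\alpha = Q/A}. The result is reported in percent
#' and clipped into (0, 100] with a flag if clipping occurred.
#'
#' @param A fitted amplitude (concentration scale), > 0
#' @param Q injected amount (nmol), > 0
#' @return list with `alphaPct` and `clipped`
#' @examples
#' deriveAlpha(A = 20 / 0.18, Q = 20)$alphaPct  # 18
#' @export
deriveAlpha <- function(A, Q) {
  if (length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive amplitude")
  if (Q <= 0) stop("'Q' must be positive")
  alpha <- 100 * Q / A
  clipped <- FALSE
  if (alpha > 100) { alpha <- 100; clipped <- TRUE }
  list(alphaPct = alpha, clipped = clipped)
}

#' Moment-based initialization of the diffusion fit
#'
#' For a free-space Gaussian tracer cloud the per-axis spatial variance of
#' the concentration grows linearly, \eqn{\mathrm{Var}_i(t) = 2 D_i t +
#' c_i}, and the total signal decays as \eqn{e^{-kt}}. Regressing the
#' measured variances on time and the log total signal on time gives
#' starting values for all parameters without any nonlinear solve. If a
#' variance regression has non-positive slope the fixed fallback start is
#' used for that axis and the result is flagged.
#'
#' @param values 4D array of (baseline-subtracted) intensities, or a
#'   [ConcentrationField]
#' @param grid [Grid3D] (ignored when `values` is a field)
#' @param times post-injection times matching the 4th dimension
#' @param fallbackD fallback diffusion coefficient (mm^2/min)
#' @return list with `D` (length-3, per axis), `k`, `fallback` (logical)
#' @export
momentsInit <- function(values, grid = NULL, times = NULL,
                        fallbackD = 0.02) {
  if (is(values, "ConcentrationField")) {
    grid <- values@grid
    times <- values@times
    values <- values@values
  }
  stopifnot(is(grid, "Grid3D"), length(times) == dim(values)[4L])
  if (length(times) < 2L) stop("need at least two snapshots")
  nt <- length(times)
  coords <- lapply(1:3, function(a) axisCoords(grid, a))
  vars <- matrix(NA_real_, nt, 3L)
  tot <- numeric(nt)
  for (j in seq_len(nt)) {
    v <- values[, , , j]
    v[v < 0] <- 0
    s <- sum(v)
    tot[j] <- s
    if (s <= 0) next
    for (a in 1:3) {
      marg <- apply(v, a, sum) / s
      mu <- sum(coords[[a]] * marg)
      vars[j, a] <- sum((coords[[a]] - mu)^2 * marg)
    }
  }
  ok <- tot > 0 & stats::complete.cases(vars)
  if (sum(ok) < 2L) stop("fewer than two usable snapshots")
  D <- numeric(3L)
  fallback <- FALSE
  for (a in 1:3) {
    slope <- stats::coef(stats::lm(vars[ok, a] ~ times[ok]))[2L]
    if (!is.finite(slope) || slope <= 0) {
      D[a] <- fallbackD
      fallback <- TRUE
    } else D[a] <- slope / 2
  }
  kslope <- stats::coef(stats::lm(log(tot[ok]) ~ times[ok]))[2L]
  k <- max(0, -kslope)
  list(D = unname(D), k = unname(k), fallback = fallback)
}

## Gaussian-kernel model prediction for the residual function:
## A * exp(-sum ri^2/(4 Di t) - k t) / (8 (pi t)^{3/2} sqrt(Dx Dy Dz)).
## `d2` is an nVox x 3 matrix of squared displacements, `tt` the times.
.kernelPredict <- function(d2, tt, Dx, Dy, Dz, k, A) {
  nv <- nrow(d2)
  pred <- matrix(0, nv, length(tt))
  for (j in seq_along(tt)) {
    t <- tt[j]
    amp <- A * exp(-k * t) / (8 * (pi * t)^1.5 * sqrt(Dx * Dy * Dz))
    pred[, j] <- amp * exp(-(d2[, 1L] / (4 * Dx * t) +
                             d2[, 2L] / (4 * Dy * t) +
                             d2[, 3L] / (4 * Dz * t)))
  }
  pred
}

#' Fit the diffusion--clearance model to a tracer study
#'
#' Estimates the ECS parameter quartet by nonlinear least squares: the
#' closed-form point-source solution is fitted to the baseline-subtracted
#' voxel enhancements across all post-injection scan times with the
#' Levenberg--Marquardt algorithm under box constraints. Free parameters
#' are the (isotropic or per-axis) diffusion coefficient, the clearance
#' rate k and the source amplitude A; the volume fraction follows as
#' alpha = Q/A ([deriveAlpha()]) and the half-life is measured on the ROI
#' mean-enhancement curve ([computeHalfLife()]; default ROI a 4 mm
#' [sphereROI()] at the injection site), with the model-implied
#' whole-domain value ln(2)/k reported alongside.
#'
#' For Rician (magnitude) noise a naive least-squares fit is biased: the
#' noise floor inflates weak signals, and selecting voxels by their own
#' noisy peak preferentially keeps upward noise excursions. The fit
#' therefore switches to an unbiased second-moment objective -- since
#' \eqn{E[S^2] = s^2 + 2\sigma^2} exactly for magnitude data, residuals
#' \eqn{(\hat s^2 - 2\sigma^2) - \mathrm{pred}^2} have mean zero at the
#' true parameters -- solved by iteratively reweighted least squares with
#' weights \eqn{1/\mathrm{SD}(S^2)} frozen between rounds, over voxels
#' selected where the initial model (not the data) predicts a peak above
#' `predFloor` noise SDs. Noiseless and Gaussian-noise studies use the
#' plain enhancement objective over voxels whose peak enhancement exceeds
#' `snrThreshold` baseline-noise SDs.
#'
#' For relaxivity-mode studies the enhancement is first inverted to
#' concentration voxelwise, so the kernel fit is always linear in A.
#' The fit is deterministic given the data and options. Non-convergence is
#' flagged on the result, never silent; degenerate (all-zero) data is an
#' error.
#'
#' @param study [TracerStudy]
#' @param roi mask for the half-life timecourse (default: 4 mm sphere at
#'   the injection site; the voxel selection for the kernel fit is
#'   independent of this mask)
#' @param opts [FitOptions]
#' @return an [ECSResult]
#' @examples
#' st <- makeAnimal(DiffusionParams(0.02, k = 0.008, alpha = 0.18),
#'                  grid = Grid3D(24, 0.5), times = c(0, 15, 30, 60, 120),
#'                  noise = NoiseModel("none"))
#' fitDiffusionModel(st)
#' @export
fitDiffusionModel <- function(study, roi = NULL, opts = FitOptions()) {
  stopifnot(is(study, "TracerStudy"), is(opts, "FitOptions"))
  validObject(study)
  tt <- study@times[-1L]
  if (length(tt) < 2L)
    stop("need at least two post-injection time points")
  d <- dim(study@signal)
  sigma <- .estimateNoiseSD(study)
  rician <- study@noise@kind == "rician" && sigma > 0
  S <- study@signal[, , , -1L, drop = FALSE]
  if (all(S == 0)) stop("degenerate data: all signals are zero")
  ## working amplitude array (bias-corrected for Rician data)
  if (rician) {
    E <- .ricianCorrect(S, sigma)
  } else {
    E <- S - array(study@signal[, , , 1L], c(d[1:3], length(tt)))
  }
  if (study@signalParams@mode == "relaxivity") {
    E[E < 0] <- 0
    E[] <- enhancementToConcentration(as.vector(E), study@signalParams)
    kappa <- 1
  } else kappa <- study@signalParams@kappa
  ## initialization
  fallback <- FALSE
  if (opts@init == "moments") {
    mi <- tryCatch(momentsInit(E, study@grid, tt,
                               fallbackD = opts@fixedInit[["D"]]),
                   error = function(e) NULL)
    if (is.null(mi)) {
      D0 <- rep(opts@fixedInit[["D"]], 3L)
      k0 <- opts@fixedInit[["k"]]
      fallback <- TRUE
    } else {
      D0 <- mi$D; k0 <- mi$k; fallback <- mi$fallback
    }
  } else {
    D0 <- rep(opts@fixedInit[["D"]], 3L)
    k0 <- opts@fixedInit[["k"]]
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  D0 <- clamp(D0, opts@lower[["D"]], opts@upper[["D"]])
  k0 <- clamp(k0, opts@lower[["k"]], opts@upper[["k"]])
  A0 <- opts@fixedInit[["A"]]
  if (is.na(A0)) {
    vv <- voxelVolume(study@grid)
    e1 <- E[, , , 1L]
    A0 <- max(sum(e1[e1 > 0]) * vv * exp(k0 * tt[1L]),
              opts@lower[["A"]] * 2)
  }
  ## voxel selection
  ctr <- study@protocol@site
  xs <- axisCoords(study@grid, 1L) - ctr[1L]
  ys <- axisCoords(study@grid, 2L) - ctr[2L]
  zs <- axisCoords(study@grid, 3L) - ctr[3L]
  r2g <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  peakE <- apply(E, 1:3, max)
  if (rician) {
    ## radius at which the *initial model's* peak falls to predFloor sigma
    rmax <- sqrt(max(r2g))
    rgrid <- seq(0, rmax, length.out = 256L)
    pk <- vapply(rgrid, function(r)
      max(.kernelPredict(matrix(c(r^2, 0, 0), 1L), tt, mean(D0), mean(D0),
                         mean(D0), k0, A0 * kappa)), numeric(1))
    above <- which(pk > opts@predFloor * sigma)
    Rsel <- if (length(above)) rgrid[max(above)] else rgrid[8L]
    informative <- which(r2g <= Rsel^2)
    if (length(informative) > opts@maxVoxels)
      informative <- informative[
        order(r2g[informative])[seq_len(opts@maxVoxels)]]
  } else {
    thr <- if (sigma > 0) opts@snrThreshold * sigma else 1e-8 * max(peakE)
    informative <- which(peakE > thr)
    if (length(informative) > opts@maxVoxels) {
      keep <- order(peakE[informative], decreasing = TRUE)[
        seq_len(opts@maxVoxels)]
      informative <- sort(informative[keep])
    }
  }
  if (length(informative) < 10L)
    stop(sprintf("only %d informative voxels (need >= 10)",
                 length(informative)))
  iv <- arrayInd(informative, d[1:3])
  d2 <- cbind(xs[iv[, 1L]]^2, ys[iv[, 2L]]^2, zs[iv[, 3L]]^2)
  ## assemble data matrix (voxels x times)
  Ym <- matrix(0, length(informative), length(tt))
  if (rician) {
    for (j in seq_along(tt))
      Ym[, j] <- study@signal[, , , j + 1L][informative]^2
    yvec <- as.vector(Ym) - 2 * sigma^2
  } else {
    for (j in seq_along(tt)) Ym[, j] <- E[, , , j][informative]
    yvec <- as.vector(Ym)
  }
  nPar <- if (opts@isotropic) 3L else 5L
  if (opts@isotropic) {
    par0 <- c(D = unname(mean(D0)), k = unname(k0), A = unname(A0))
    lower <- unname(opts@lower[c("D", "k", "A")])
    upper <- unname(opts@upper[c("D", "k", "A")])
    predFn <- function(p) as.vector(
      .kernelPredict(d2, tt, p[1L], p[1L], p[1L], p[2L], p[3L] * kappa))
  } else {
    par0 <- c(Dx = D0[1L], Dy = D0[2L], Dz = D0[3L], k = unname(k0),
              A = unname(A0))
    lower <- unname(c(rep(opts@lower[["D"]], 3L), opts@lower[["k"]],
                      opts@lower[["A"]]))
    upper <- unname(c(rep(opts@upper[["D"]], 3L), opts@upper[["k"]],
                      opts@upper[["A"]]))
    predFn <- function(p) as.vector(
      .kernelPredict(d2, tt, p[1L], p[2L], p[3L], p[4L], p[5L] * kappa))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = opts@tol, ptol = opts@tol,
                                     maxiter = opts@maxIter)
  if (rician) {
    par <- par0
    w <- rep(1, length(yvec))
    for (it in seq_len(max(1L, opts@irls))) {
      fit <- minpack.lm::nls.lm(
        par = par, lower = lower, upper = upper,
        fn = function(p) (predFn(p)^2 - yvec) * w, control = ctrl)
      par <- fit$par
      pv <- predFn(par)
      w <- 1 / sqrt(4 * sigma^2 * pv^2 + 4 * sigma^4)
    }
  } else {
    fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                              fn = function(p) predFn(p) - yvec,
                              control = ctrl)
  }
  p <- fit$par
  if (opts@isotropic) {
    Dx <- Dy <- Dz <- p[[1L]]; k <- p[[2L]]; Aconc <- p[[3L]]
  } else {
    Dx <- p[[1L]]; Dy <- p[[2L]]; Dz <- p[[3L]]; k <- p[[4L]]
    Aconc <- p[[5L]]
  }
  converged <- fit$info %in% 1:4
  rss <- fit$deviance
  ## R^2 on the amplitude scale over the selected voxels (for Rician data
  ## the raw second-moment objective is noise-dominated by design, so the
  ## bias-corrected amplitudes give the interpretable diagnostic)
  if (rician) {
    yAmp <- .ricianCorrect(sqrt(pmax(yvec + 2 * sigma^2, 0)), sigma)
    pAmp <- predFn(fit$par)
    r2 <- 1 - sum((pAmp - yAmp)^2) / sum((yAmp - mean(yAmp))^2)
  } else {
    r2 <- 1 - rss / sum((yvec - mean(yvec))^2)
  }
  al <- deriveAlpha(Aconc, amountQ(study))
  if (is.null(roi)) roi <- sphereROI(study@grid, ctr, 4)
  tc <- extractTimecourse(study, roi)
  hl <- computeHalfLife(tc)
  new("ECSResult",
      Dx = Dx, Dy = Dy, Dz = Dz, Dstar = computeDstar(Dx, Dy, Dz),
      DstarReported = internalToReportedD(computeDstar(Dx, Dy, Dz)),
      k = k, kReported = internalToReportedD(k),
      alphaPct = al$alphaPct, alphaClipped = al$clipped,
      Thalf = hl$Thalf, ThalfCensored = hl$censored,
      ThalfModel = if (k > 0) log(2) / k else Inf,
      amplitude = Aconc, rss = rss, r2 = r2,
      converged = converged, message = fit$message)
}

#' Fit every study of a cohort
#'
#' Convenience wrapper: runs [fitDiffusionModel()] on each study of a
#' [makeGroupDataset()] cohort and returns tidy per-animal rows.
#'
#' @param cohort list with `studies` (and optionally `truth`)
#' @param roi optional half-life mask passed through
#' @param opts [FitOptions]
#' @return data.frame of per-animal estimates (one row per study)
#' @export
fitCohort <- function(cohort, roi = NULL, opts = FitOptions()) {
  rows <- lapply(cohort$studies, function(st) {
    res <- fitDiffusionModel(st, roi = roi, opts = opts)
    cbind(data.frame(label = st@label), as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  out$group <- sub("_[0-9]+$", "", out$label)
  out
}
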