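#' @import methods
NULL

setClassUnion("NumericOrNULL", c("numeric", "NULL"))

#' Physical parameters of the diffusion--clearance model
#'
#' The state of the extracellular-space (ECS) tracer model: directional
#' effective diffusion coefficients \eqn{D_x, D_y, D_z} (mm^2/min), the
#' first-order clearance rate \eqn{k} (1/min) describing tracer removal by
#' interstitial-fluid drainage and metabolism, and the ECS volume fraction
#' \eqn{\alpha} (dimensionless, the fraction of tissue volume occupied by
#' extracellular fluid).
#'
#' @slot Dx,Dy,Dz effective diffusion coefficients along each axis, mm^2/min
#' @slot k clearance rate, 1/min (0 = conserved tracer)
#' @slot alpha ECS volume fraction in (0, 1]
#' @export
setClass("DiffusionParams",
  slots = c(Dx = "numeric", Dy = "numeric", Dz = "numeric",
            k = "numeric", alpha = "numeric"))

setValidity("DiffusionParams", function(object) {
  msg <- character()
  for (s in c("Dx", "Dy", "Dz", "k", "alpha")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (!length(msg)) {
    if (object@Dx <= 0 || object@Dy <= 0 || object@Dz <= 0)
      msg <- c(msg, "diffusion coefficients must be > 0")
    if (object@k < 0) msg <- c(msg, "clearance rate 'k' must be >= 0")
    if (object@alpha <= 0 || object@alpha > 1)
      msg <- c(msg, "'alpha' must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param Dx,Dy,Dz diffusion coefficients (mm^2/min); `Dy`, `Dz` default to `Dx`
#'   so `DiffusionParams(0.02)` is isotropic
#' @param k clearance rate (1/min)
#' @param alpha ECS volume fraction in (0, 1]
#' @return a `DiffusionParams` object
#' @examples
#' DiffusionParams(0.02, k = 0.01, alpha = 0.2)
#' @rdname DiffusionParams-class
#' @export
DiffusionParams <- function(Dx, Dy = Dx, Dz = Dx, k = 0, alpha = 0.2) {
  new("DiffusionParams", Dx = as.numeric(Dx), Dy = as.numeric(Dy),
      Dz = as.numeric(Dz), k = as.numeric(k), alpha = as.numeric(alpha))
}

setClassUnion("DiffusionParamsOrNULL", c("DiffusionParams", "NULL"))

#' Injected tracer source
#'
#' An injected bolus of tracer: total amount \eqn{Q} (nmol), injection site in
#' mm coordinates, onset time and infusion duration (0 means an instantaneous
#' bolus; a positive duration spreads the release uniformly over it).
#'
#' @slot amount injected amount Q, nmol
#' @slot position numeric(3), injection site (mm)
#' @slot onset injection time (min)
#' @slot duration infusion duration (min); 0 = instantaneous
#' @export
setClass("SourceBolus",
  slots = c(amount = "numeric", position = "numeric",
            onset = "numeric", duration = "numeric"))

setValidity("SourceBolus", function(object) {
  msg <- character()
  if (length(object@amount) != 1L || !is.finite(object@amount) ||
      object@amount <= 0)
    msg <- c(msg, "'amount' must be a single positive number (nmol)")
  if (length(object@position) != 3L || any(!is.finite(object@position)))
    msg <- c(msg, "'position' must be numeric(3) in mm")
  if (length(object@duration) != 1L || object@duration < 0)
    msg <- c(msg, "'duration' must be >= 0")
  if (length(object@onset) != 1L || !is.finite(object@onset))
    msg <- c(msg, "'onset' must be a single finite time (min)")
  if (length(msg)) msg else TRUE
})

#' @param amount injected amount Q (nmol)
#' @param position injection site, numeric(3) in mm
#' @param onset injection time (min)
#' @param duration infusion duration (min), 0 for an instantaneous bolus
#' @rdname SourceBolus-class
#' @export
SourceBolus <- function(amount, position = c(0, 0, 0), onset = 0,
                        duration = 0) {
  new("SourceBolus", amount = as.numeric(amount),
      position = as.numeric(position), onset = as.numeric(onset),
      duration = as.numeric(duration))
}

#' Regular 3D voxel grid
#'
#' A regular grid of voxel centers. `origin` is the mm coordinate of the
#' center of voxel (1,1,1); indices are 1-based along each axis.
#'
#' @slot shape integer(3), voxel counts per axis
#' @slot voxelSize numeric(3), voxel edge lengths (mm)
#' @slot origin numeric(3), mm coordinate of the first voxel center
#' @export
setClass("Grid3D",
  slots = c(shape = "integer", voxelSize = "numeric", origin = "numeric"))

setValidity("Grid3D", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 3L))
    msg <- c(msg, "'shape' must be integer(3) with all components >= 3")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be numeric(3) with all components > 0")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be numeric(3) (mm)")
  if (length(msg)) msg else TRUE
})

#' @param shape voxel counts per axis (length 1 or 3)
#' @param voxelSize voxel edge length(s) in mm (length 1 or 3)
#' @param origin mm coordinate of the first voxel center; by default the grid
#'   is centered on (0, 0, 0)
#' @examples
#' Grid3D(48, 0.5)   # 24 mm cube centered at the origin
#' @rdname Grid3D-class
#' @export
Grid3D <- function(shape, voxelSize = 0.5, origin = NULL) {
  shape <- as.integer(rep_len(shape, 3L))
  voxelSize <- as.numeric(rep_len(voxelSize, 3L))
  if (is.null(origin))
    origin <- -(shape - 1L) / 2 * voxelSize
  new("Grid3D", shape = shape, voxelSize = voxelSize,
      origin = as.numeric(origin))
}

#' Tracer concentration over a grid and time
#'
#' Concentration C(x, y, z, t) in mM sampled on a [Grid3D] at an increasing
#' set of times (min), stored as a 4D array (x, y, z, time).
#'
#' @slot times scan times (min), strictly increasing
#' @slot values 4D array of concentrations (mM), non-negative
#' @slot grid the [Grid3D] the field lives on
#' @export
setClass("ConcentrationField",
  slots = c(times = "numeric", values = "array", grid = "Grid3D"))

setValidity("ConcentrationField", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L)
    msg <- c(msg, "'values' must be a 4D array (x, y, z, time)")
  else {
    if (!all(d[1:3] == object@grid@shape))
      msg <- c(msg, "spatial dimensions of 'values' do not match the grid")
    if (d[4L] != length(object@times))
      msg <- c(msg, "4th dimension of 'values' must match length(times)")
  }
  if (length(object@times) < 1L ||
      (length(object@times) > 1L && any(diff(object@times) <= 0)))
    msg <- c(msg, "'times' must be non-empty and strictly increasing")
  if (any(object@values < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

ConcentrationField <- function(times, values, grid) {
  new("ConcentrationField", times = as.numeric(times), values = values,
      grid = grid)
}

#' Injection protocol
#'
#' Tracer injection protocol: infused volume (ul), tracer concentration (mM)
#' and the stereotaxic site (mm). The injected amount is their product,
#' Q = volume x concentration (nmol). Defaults emulate a 2 ul bolus of 10 mM
#' Gd-DTPA, i.e. Q = 20 nmol.
#'
#' @slot volume injected volume, ul
#' @slot concentration tracer concentration, mM
#' @slot site numeric(3) injection site in mm (AP, ML, DV convention maps to
#'   grid x, y, z; the default simulation grid puts the site at its center)
#' @export
setClass("InjectionProtocol",
  slots = c(volume = "numeric", concentration = "numeric", site = "numeric"))

setValidity("InjectionProtocol", function(object) {
  msg <- character()
  if (object@volume <= 0 || object@concentration <= 0)
    msg <- c(msg, "volume and concentration must be positive")
  if (length(object@site) != 3L)
    msg <- c(msg, "'site' must be numeric(3) (mm)")
  if (length(msg)) msg else TRUE
})

#' @param volume injected volume (ul)
#' @param concentration tracer concentration (mM)
#' @param site injection site, numeric(3) mm
#' @rdname InjectionProtocol-class
#' @export
InjectionProtocol <- function(volume = 2, concentration = 10,
                              site = c(0, 0, 0)) {
  new("InjectionProtocol", volume = as.numeric(volume),
      concentration = as.numeric(concentration), site = as.numeric(site))
}

#' Signal model parameters
#'
#' Maps tracer concentration to relative T1-weighted signal enhancement.
#' `"linear"` mode uses E = kappa * C (the small-concentration regime of a
#' gadolinium tracer); `"relaxivity"` mode computes the spoiled
#' gradient-echo steady-state signal from 1/T1 = 1/T10 + r1 * C.
#'
#' @slot mode `"linear"` or `"relaxivity"`
#' @slot kappa enhancement per mM (linear mode)
#' @slot r1 longitudinal relaxivity, 1/(mM s)
#' @slot T10 pre-contrast T1, s
#' @slot TR,TE,TI sequence times, s
#' @slot flipAngle degrees
#' @export
setClass("SignalParams",
  slots = c(mode = "character", kappa = "numeric", r1 = "numeric",
            T10 = "numeric", TR = "numeric", TE = "numeric", TI = "numeric",
            flipAngle = "numeric"))

setValidity("SignalParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("linear", "relaxivity"))
    msg <- c(msg, "mode must be 'linear' or 'relaxivity'")
  if (object@kappa <= 0) msg <- c(msg, "'kappa' must be > 0")
  if (object@r1 <= 0) msg <- c(msg, "'r1' must be > 0")
  if (object@T10 <= 0) msg <- c(msg, "'T10' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param mode `"linear"` or `"relaxivity"`
#' @param kappa enhancement per mM in linear mode
#' @param r1 relaxivity (1/(mM s)); default 3.6 is literature-typical for
#'   Gd-DTPA at 3 T
#' @param T10 pre-contrast tissue T1 (s)
#' @param TR,TE,TI sequence times (s); defaults follow a 3 T T1-weighted
#'   acquisition (TE 3.7 ms, TR 1500 ms, TI 900 ms)
#' @param flipAngle degrees
#' @rdname SignalParams-class
#' @export
SignalParams <- function(mode = c("linear", "relaxivity"), kappa = 1,
                         r1 = 3.6, T10 = 1.6, TR = 1.5, TE = 0.0037,
                         TI = 0.9, flipAngle = 12) {
  mode <- match.arg(mode)
  new("SignalParams", mode = mode, kappa = as.numeric(kappa),
      r1 = as.numeric(r1), T10 = as.numeric(T10), TR = as.numeric(TR),
      TE = as.numeric(TE), TI = as.numeric(TI),
      flipAngle = as.numeric(flipAngle))
}

#' Measurement noise model
#'
#' Magnitude-MRI noise: `"rician"` draws sqrt((S + n1)^2 + n2^2) with
#' independent Normal(0, sigma) components (the magnitude-image convention),
#' `"gaussian"` adds a single component, `"none"` is the identity.
#'
#' @slot kind `"rician"`, `"gaussian"` or `"none"`
#' @slot sigma noise SD in signal units
#' @slot seed integer RNG seed (NA = use the current RNG stream)
#' @export
setClass("NoiseModel",
  slots = c(kind = "character", sigma = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("rician", "gaussian", "none"))
    msg <- c(msg, "kind must be 'rician', 'gaussian' or 'none'")
  if (length(object@sigma) != 1L ||
      (!is.na(object@sigma) && object@sigma < 0))
    msg <- c(msg, "'sigma' must be a single number >= 0 (or NA = derive)")
  if (length(msg)) msg else TRUE
})

#' @param kind noise kind
#' @param sigma noise SD (signal units)
#' @param seed integer seed, or NA to draw from the current RNG stream
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(kind = c("rician", "gaussian", "none"), sigma = 0,
                       seed = NA_integer_) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' A tracer-enhanced MRI study
#'
#' One (simulated or observed) animal: a 4D relative-enhancement series on a
#' [Grid3D] at scan times that include a pre-injection baseline (t = 0), plus
#' the injection protocol, signal and noise models, and -- for synthetic
#' studies -- the ground-truth [DiffusionParams].
#'
#' @slot signal 4D array (x, y, z, time) of measured signal (relative
#'   enhancement units)
#' @slot grid [Grid3D]
#' @slot times scan times in min, first element 0 (baseline)
#' @slot protocol [InjectionProtocol]
#' @slot signalParams [SignalParams]
#' @slot noise [NoiseModel]
#' @slot truth ground-truth [DiffusionParams], or NULL for real data
#' @slot label character study label
#' @export
setClass("TracerStudy",
  slots = c(signal = "array", grid = "Grid3D", times = "numeric",
            protocol = "InjectionProtocol", signalParams = "SignalParams",
            noise = "NoiseModel", truth = "DiffusionParamsOrNULL",
            label = "character"))

setValidity("TracerStudy", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4L)
    msg <- c(msg, "'signal' must be a 4D array (x, y, z, time)")
  else {
    if (!all(d[1:3] == object@grid@shape))
      msg <- c(msg, "signal spatial dimensions do not match the grid")
    if (d[4L] != length(object@times))
      msg <- c(msg, "signal time dimension does not match length(times)")
  }
  if (length(object@times) < 1L || object@times[1L] != 0 ||
      any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must start with a t = 0 baseline and increase")
  if (length(msg)) msg else TRUE
})

#' ROI mean-enhancement timecourse
#'
#' Baseline-subtracted mean signal enhancement over a region of interest.
#'
#' @slot times scan times (min)
#' @slot enhancement mean enhancement per time
#' @slot nVoxels voxels in the ROI
#' @slot label ROI label
#' @export
setClass("ROITimecourse",
  slots = c(times = "numeric", enhancement = "numeric", nVoxels = "integer",
            label = "character"))

setValidity("ROITimecourse", function(object) {
  msg <- character()
  if (length(object@times) != length(object@enhancement))
    msg <- c(msg, "'times' and 'enhancement' lengths differ")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(!is.finite(object@enhancement)))
    msg <- c(msg, "enhancement values must be finite")
  if (length(msg)) msg else TRUE
})

#' Fitted ECS parameter quartet
#'
#' Result of fitting the diffusion--clearance model to a tracer study: the
#' effective diffusion coefficient D* (geometric mean of the axis
#' coefficients), clearance coefficient k', half-life T1/2 of the ROI mean
#' enhancement, and ECS volume fraction alpha, with fit diagnostics.
#' Internal units are mm^2/min and 1/min; `DstarReported`/`kReported` carry the
#' reporting-scale values (see [internalToReportedD()]).
#'
#' @slot Dx,Dy,Dz fitted axis diffusion coefficients, mm^2/min
#' @slot Dstar geometric-mean diffusion coefficient, mm^2/min
#' @slot DstarReported D* on the reporting scale
#' @slot k fitted clearance rate, 1/min
#' @slot kReported k' on the reporting scale
#' @slot alphaPct ECS volume fraction, percent
#' @slot alphaClipped TRUE if alpha was clipped into (0, 100]
#' @slot Thalf half-life of the ROI mean-enhancement curve, min (time from
#'   peak to half-peak)
#' @slot ThalfCensored TRUE if the half level was not reached in the schedule
#'   (then Thalf is the censoring lower bound)
#' @slot ThalfModel model-implied whole-domain half-life ln(2)/k, min
#' @slot amplitude fitted concentration-scale amplitude A = Q/alpha
#' @slot rss residual sum of squares
#' @slot r2 coefficient of determination
#' @slot converged logical
#' @slot message solver message
#' @export
setClass("ECSResult",
  slots = c(Dx = "numeric", Dy = "numeric", Dz = "numeric",
            Dstar = "numeric", DstarReported = "numeric",
            k = "numeric", kReported = "numeric",
            alphaPct = "numeric", alphaClipped = "logical",
            Thalf = "numeric", ThalfCensored = "logical",
            ThalfModel = "numeric",
            amplitude = "numeric", rss = "numeric", r2 = "numeric",
            converged = "logical", message = "character"))

setValidity("ECSResult", function(object) {
  msg <- character()
  if (object@Dstar <= 0) msg <- c(msg, "'Dstar' must be > 0")
  if (object@k < 0) msg <- c(msg, "'k' must be >= 0")
  if (object@Thalf <= 0) msg <- c(msg, "'Thalf' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fit options for the ECS parameter estimator
#'
#' @slot isotropic fit a single D (TRUE) or per-axis Dx, Dy, Dz (FALSE)
#' @slot lower,upper named bounds for `D` (mm^2/min), `k` (1/min) and the
#'   amplitude `A`
#' @slot init `"moments"` (spatial-moment initialization) or `"fixed"`
#' @slot fixedInit named start values used when `init = "fixed"` or as
#'   fallback
#' @slot tol relative convergence tolerance passed to the least-squares
#'   solver
#' @slot maxIter maximum solver iterations
#' @slot maxVoxels cap on informative voxels entering the fit (the
#'   highest-peak voxels are kept; deterministic)
#' @slot snrThreshold informative-voxel criterion: peak enhancement must
#'   exceed this multiple of the baseline noise SD
#' @slot predFloor for Rician data, voxels are selected where the
#'   initial-model peak prediction exceeds `predFloor` noise SDs (selection
#'   on the model rather than on a voxel's own noise avoids selection bias)
#' @slot irls number of iteratively reweighted rounds for the Rician
#'   second-moment objective
#' @export
setClass("FitOptions",
  slots = c(isotropic = "logical", lower = "numeric", upper = "numeric",
            init = "character", fixedInit = "numeric", tol = "numeric",
            maxIter = "integer", maxVoxels = "integer",
            snrThreshold = "numeric", predFloor = "numeric",
            irls = "integer"))

#' @param isotropic single-D fit (default) or per-axis
#' @param lower,upper named numeric bounds with elements `D`, `k`, `A`
#' @param init `"moments"` or `"fixed"`
#' @param fixedInit named start values (`D`, `k`, `A`); `A` of NA is derived
#'   from the data
#' @param tol solver relative tolerance
#' @param maxIter maximum iterations
#' @param maxVoxels cap on voxels entering the fit
#' @param snrThreshold informative-voxel threshold (multiples of baseline
#'   noise SD)
#' @param predFloor model-based selection floor for Rician data (noise SDs)
#' @param irls reweighting rounds for the Rician objective
#' @rdname FitOptions-class
#' @export
FitOptions <- function(isotropic = TRUE,
                       lower = c(D = 1e-4, k = 0, A = 1e-8),
                       upper = c(D = 1, k = 0.2, A = Inf),
                       init = c("moments", "fixed"),
                       fixedInit = c(D = 0.02, k = 0.01, A = NA),
                       tol = 1e-10, maxIter = 150L, maxVoxels = 4000L,
                       snrThreshold = 3, predFloor = 0.2, irls = 3L) {
  init <- match.arg(init)
  stopifnot(all(c("D", "k", "A") %in% names(lower)),
            all(c("D", "k", "A") %in% names(upper)))
  obj <- new("FitOptions", isotropic = isotropic, lower = lower,
             upper = upper, init = init, fixedInit = fixedInit,
             tol = tol, maxIter = as.integer(maxIter),
             maxVoxels = as.integer(maxVoxels), snrThreshold = snrThreshold,
             predFloor = predFloor, irls = as.integer(irls))
  st <- obj@fixedInit
  ok <- is.na(st["A"]) || (st["A"] >= lower["A"] && st["A"] <= upper["A"])
  if (st["D"] < lower["D"] || st["D"] > upper["D"] ||
      st["k"] < lower["k"] || st["k"] > upper["k"] || !ok)
    stop("fit bounds must contain the start values")
  obj
}

#' Design of one simulated study group
#'
#' Group-level ground-truth distributions on the reporting scale (mean and SD
#' of D*, T1/2, k' and alpha as they would be tabulated), the number of
#' animals and the simulation machinery (protocol, grid, schedule, signal
#' and noise settings). The physical clearance rate of each simulated animal
#' is back-derived from its sampled half-life, k = ln(2)/T1/2, so the
#' whole-domain half-life of the simulated tracer matches the design.
#'
#' @slot label group label
#' @slot mean,sd named numeric vectors with elements `Dstar`, `Thalf`,
#'   `kprime`, `alpha` (reporting units: D*/k' on the display scale, T1/2 in
#'   min, alpha in percent)
#' @slot n animals per group
#' @slot protocol [InjectionProtocol]
#' @slot grid [Grid3D]
#' @slot times scan schedule (min), starting at the t = 0 baseline
#' @slot signalParams [SignalParams]
#' @slot noiseKind `"rician"`, `"gaussian"` or `"none"`
#' @slot peakSNR target peak signal-to-noise ratio (noise SD is set to
#'   peak noiseless signal / peakSNR); ignored when `noiseKind = "none"`
#' @export
setClass("StudyDesign",
  slots = c(label = "character", mean = "numeric", sd = "numeric",
            n = "integer", protocol = "InjectionProtocol", grid = "Grid3D",
            times = "numeric", signalParams = "SignalParams",
            noiseKind = "character", peakSNR = "numeric"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  need <- c("Dstar", "Thalf", "kprime", "alpha")
  if (!all(need %in% names(object@mean)) ||
      !all(need %in% names(object@sd)))
    msg <- c(msg, "mean/sd must be named vectors with Dstar, Thalf, kprime, alpha")
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (any(object@sd < 0)) msg <- c(msg, "SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Voxelwise diffusion-parameter map
#'
#' A 3D map of the locally fitted diffusion parameter (Decs/ADCe). Voxels
#' where the informative-voxel criterion fails are NA (masked), never
#' zero-filled.
#'
#' @slot values 3D array; NA = masked
#' @slot grid [Grid3D]
#' @slot units character unit string
#' @export
setClass("ParamMap",
  slots = c(values = "array", grid = "Grid3D", units = "character"))

setValidity("ParamMap", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || !all(d == object@grid@shape))
    msg <- c(msg, "'values' must be a 3D array matching the grid")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msg <- c(msg, "unmasked map values must be finite")
  if (length(msg)) msg else TRUE
})
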