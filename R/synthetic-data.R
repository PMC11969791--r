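#' @include AllClasses.R forward-model.R signal-model.R reference-tables.R
NULL

#' Default acquisition schedule
#'
#' Scan times in minutes: a pre-injection baseline at t = 0 followed by
#' scans out to the 240-min horizon over which a healthy substantia nigra
#' clears the tracer.
#'
#' @return numeric vector of scan times (min)
#' @export
defaultSchedule <- function() c(0, 15, 30, 60, 90, 120, 180, 240)

#' Simulate one tracer study
#'
#' Composes the forward model and the signal model: evaluates the analytic
#' concentration field for the ground-truth parameters at all post-baseline
#' scan times, maps concentration to relative enhancement, and adds
#' magnitude noise. The baseline volume is the zero-enhancement image (plus
#' noise). The ground truth is attached to the returned study.
#'
#' @param truth [DiffusionParams] ground truth
#' @param protocol [InjectionProtocol]; the bolus (amount Q = volume x
#'   concentration) is released instantaneously at t = 0 at `protocol@site`
#'   (grid coordinates, mm)
#' @param grid [Grid3D]
#' @param times scan schedule (min); must start with a t = 0 baseline
#' @param signalParams [SignalParams]
#' @param noise [NoiseModel]; a `sigma` of NA is resolved to
#'   `max(noiseless signal) / peakSNR`
#' @param peakSNR target peak SNR used when `noise@sigma` is NA
#' @param seed optional integer; if given, the noise draw is seeded (the
#'   caller's RNG state is preserved)
#' @param label study label
#' @return a [TracerStudy]
#' @examples
#' st <- makeAnimal(DiffusionParams(0.02, k = 0.01, alpha = 0.18),
#'                  grid = Grid3D(24, 0.5), times = c(0, 30, 60, 120),
#'                  noise = NoiseModel("none"))
#' @export
makeAnimal <- function(truth, protocol = InjectionProtocol(),
                       grid = Grid3D(48, 0.5), times = defaultSchedule(),
                       signalParams = SignalParams(),
                       noise = NoiseModel("none"), peakSNR = 20,
                       seed = NA_integer_, label = "synthetic") {
  stopifnot(is(truth, "DiffusionParams"), is(protocol, "InjectionProtocol"))
  times <- as.numeric(times)
  if (length(times) < 2L || times[1L] != 0)
    stop("'times' must start with a t = 0 pre-injection baseline")
  bolus <- SourceBolus(amountQ(protocol), position = protocol@site)
  field <- evaluateField(truth, bolus, grid, times[-1L])
  E <- concentrationToEnhancement(fieldValues(field), signalParams)
  signal <- array(0, c(grid@shape, length(times)))
  signal[, , , -1L] <- E
  if (noise@kind != "none" && is.na(noise@sigma))
    noise@sigma <- sigmaForPeakSNR(signal, peakSNR)
  if (!is.na(seed)) noise@seed <- as.integer(seed)
  signal <- addNoise(signal, noise)
  new("TracerStudy", signal = signal, grid = grid, times = times,
      protocol = protocol, signalParams = signalParams, noise = noise,
      truth = truth, label = label)
}

#' Construct a study-group design
#'
#' @param label group label
#' @param mean,sd named numeric vectors with elements `Dstar`, `Thalf`,
#'   `kprime`, `alpha` on the reporting scale (see [StudyDesign-class])
#' @param n animals
#' @param protocol [InjectionProtocol]
#' @param grid [Grid3D]
#' @param times scan schedule
#' @param signalParams [SignalParams]
#' @param noiseKind `"rician"`, `"gaussian"` or `"none"`
#' @param peakSNR target peak SNR
#' @return a [StudyDesign]
#' @export
StudyDesign <- function(label, mean, sd, n = 6L,
                        protocol = InjectionProtocol(),
                        grid = Grid3D(48, 0.5), times = defaultSchedule(),
                        signalParams = SignalParams(),
                        noiseKind = "rician", peakSNR = 20) {
  new("StudyDesign", label = label, mean = mean, sd = sd, n = as.integer(n),
      protocol = protocol, grid = grid, times = times,
      signalParams = signalParams, noiseKind = noiseKind, peakSNR = peakSNR)
}

#' Ground-truth parameter presets for the standard study groups
#'
#' Builds [StudyDesign] presets whose reporting-scale means and SDs equal
#' the reference group rows of [referenceECSSummaries()]: a sham-like, a
#' PD-like (6-OHDA-lesioned) and an ST-like (lesioned + stimulated) group.
#' The physical ground truth of each simulated animal is derived from its
#' sampled reporting-scale values: D (mm^2/min) from D* via
#' [reportedToInternalD()], the clearance rate from the sampled half-life
#' (k = ln 2 / T1/2, so the simulated whole-domain half-life matches the
#' design), and the volume fraction from alpha (%).
#'
#' @param groups which presets to return (subset of `"sham"`, `"pd"`,
#'   `"nst"`, `"st"`)
#' @param n animals per group
#' @param grid [Grid3D] for the simulations
#' @param times scan schedule
#' @param noiseKind noise kind for simulated studies
#' @param peakSNR target peak SNR
#' @param signalParams [SignalParams]
#' @return named list of [StudyDesign]
#' @examples
#' d <- defaultDesigns()
#' d$sham
#' @export
defaultDesigns <- function(groups = c("sham", "pd", "st"), n = 6L,
                           grid = Grid3D(48, 0.5),
                           times = defaultSchedule(),
                           noiseKind = "rician", peakSNR = 20,
                           signalParams = SignalParams()) {
  ref <- referenceECSSummaries()
  groups <- match.arg(groups, c("sham", "pd", "nst", "st"),
                      several.ok = TRUE)
  out <- lapply(groups, function(g) {
    rows <- ref[ref$group == g, ]
    m <- stats::setNames(rows$mean, rows$parameter)
    s <- stats::setNames(rows$sd, rows$parameter)
    StudyDesign(label = g, mean = m, sd = s, n = n, grid = grid,
                times = times, signalParams = signalParams,
                noiseKind = noiseKind, peakSNR = peakSNR)
  })
  stats::setNames(out, groups)
}

## Draw one truncated-normal value by resampling (physical bounds).
.rtruncResample <- function(mean, sd, lower, upper, maxTries = 1000L) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in seq_len(maxTries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower && x <= upper) return(x)
  }
  stop("truncated sampling failed; check design means/SDs")
}

#' Sample the ground truth of one animal from a design
#'
#' @param design [StudyDesign]
#' @return list with the sampled reporting-scale values (`Dstar`, `Thalf`,
#'   `alpha`) and the physical `params` ([DiffusionParams])
#' @export
sampleTruth <- function(design) {
  Dstar <- .rtruncResample(design@mean["Dstar"], design@sd["Dstar"],
                           0, Inf)
  Thalf <- .rtruncResample(design@mean["Thalf"], design@sd["Thalf"],
                           0, Inf)
  alpha <- .rtruncResample(design@mean["alpha"], design@sd["alpha"],
                           0, 100)
  D <- reportedToInternalD(Dstar)
  k <- log(2) / Thalf
  list(Dstar = unname(Dstar), Thalf = unname(Thalf),
       alpha = unname(alpha),
       params = DiffusionParams(D, k = k, alpha = alpha / 100))
}

#' Simulate a cohort of tracer studies
#'
#' Draws per-animal ground truths from each design's reporting-scale (mean,
#' SD), truncated to physical ranges by resampling, simulates every animal
#' with [makeAnimal()], and returns the studies together with a
#' ground-truth table. Fully reproducible from `seed`: all draws (truths and
#' noise) flow from one RNG stream.
#'
#' @param designs list of [StudyDesign] (e.g. [defaultDesigns()])
#' @param seed integer seed
#' @return list with elements `studies` (list of [TracerStudy]) and `truth`
#'   (data.frame: group, animal, reporting-scale truths and internal-unit
#'   truths)
#' @export
makeGroupDataset <- function(designs, seed = 1L) {
  stopifnot(length(designs) >= 1L)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  studies <- list()
  rows <- list()
  for (design in designs) {
    stopifnot(is(design, "StudyDesign"))
    validObject(design)
    for (i in seq_len(design@n)) {
      tr <- sampleTruth(design)
      noise <- NoiseModel(design@noiseKind, sigma = NA_real_)
      study <- makeAnimal(tr$params, protocol = design@protocol,
                          grid = design@grid, times = design@times,
                          signalParams = design@signalParams,
                          noise = noise, peakSNR = design@peakSNR,
                          label = sprintf("%s_%02d", design@label, i))
      studies[[length(studies) + 1L]] <- study
      rows[[length(rows) + 1L]] <- data.frame(
        group = design@label, animal = i,
        Dstar = tr$Dstar, Thalf = tr$Thalf, alpha = tr$alpha,
        D = tr$params@Dx, k = tr$params@k,
        alphaFrac = tr$params@alpha)
    }
  }
  list(studies = studies, truth = do.call(rbind, rows))
}
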