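#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics used across the package: `scanTimes()` returns the
#' time axis (min), `fieldValues()` the underlying array, `studyGrid()` the
#' [Grid3D], `groundTruth()` the attached ground truth (or NULL), and
#' `amountQ()` the injected tracer amount in nmol.
#'
#' @param object an ecstracer object
#' @return see details per class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("studyGrid", function(object) standardGeneric("studyGrid"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("amountQ", function(object) standardGeneric("amountQ"))

#' @rdname accessors
#' @export
setMethod("scanTimes", "ConcentrationField", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("scanTimes", "TracerStudy", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("scanTimes", "ROITimecourse", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("fieldValues", "ConcentrationField", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("fieldValues", "TracerStudy", function(object) object@signal)

#' @rdname accessors
#' @export
setMethod("fieldValues", "ParamMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("studyGrid", "ConcentrationField", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("studyGrid", "TracerStudy", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("studyGrid", "ParamMap", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("groundTruth", "TracerStudy", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("amountQ", "InjectionProtocol",
          function(object) object@volume * object@concentration)

#' @rdname accessors
#' @export
setMethod("amountQ", "TracerStudy", function(object) amountQ(object@protocol))

#' @rdname accessors
#' @export
setMethod("amountQ", "SourceBolus", function(object) object@amount)

setMethod("show", "DiffusionParams", function(object) {
  cat(sprintf(
    "DiffusionParams: D = (%.4g, %.4g, %.4g) mm^2/min, k = %.4g /min, alpha = %.3g\n",
    object@Dx, object@Dy, object@Dz, object@k, object@alpha))
})

setMethod("show", "Grid3D", function(object) {
  cat(sprintf("Grid3D: %d x %d x %d voxels of %.3g x %.3g x %.3g mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
})

setMethod("show", "ConcentrationField", function(object) {
  cat(sprintf(
    "ConcentrationField: %d x %d x %d voxels, %d time point(s) (%.4g-%.4g min), max %.4g mM\n",
    dim(object@values)[1], dim(object@values)[2], dim(object@values)[3],
    length(object@times), min(object@times), max(object@times),
    max(object@values)))
})

setMethod("show", "TracerStudy", function(object) {
  cat(sprintf(
    "TracerStudy '%s': %d x %d x %d voxels, %d scans (0-%g min), Q = %g nmol, noise = %s%s\n",
    object@label, object@grid@shape[1], object@grid@shape[2],
    object@grid@shape[3], length(object@times), max(object@times),
    amountQ(object), object@noise@kind,
    if (is.null(object@truth)) "" else ", ground truth attached"))
})

setMethod("show", "ECSResult", function(object) {
  cat("ECSResult (tracer-based ECS parameter fit)\n")
  cat(sprintf("  D*    : %.4g mm^2/min (%.3g reporting units)\n",
              object@Dstar, object@DstarReported))
  cat(sprintf("  k'    : %.4g /min (%.3g reporting units)\n",
              object@k, object@kReported))
  cat(sprintf("  T1/2  : %.4g min%s (model ln2/k = %.4g min)\n",
              object@Thalf,
              if (object@ThalfCensored) " (right-censored)" else "",
              object@ThalfModel))
  cat(sprintf("  alpha : %.4g %%%s\n", object@alphaPct,
              if (object@alphaClipped) " (clipped)" else ""))
  cat(sprintf("  fit   : RSS %.4g, R^2 %.4f, %s\n", object@rss, object@r2,
              if (object@converged) "converged" else
                paste("NOT converged:", object@message)))
})

setMethod("show", "ROITimecourse", function(object) {
  cat(sprintf(
    "ROITimecourse '%s': %d voxels, %d times, peak %.4g at %g min\n",
    object@label, object@nVoxels, length(object@times),
    max(object@enhancement),
    object@times[which.max(object@enhancement)]))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign '%s': n = %d, D* %.3g+/-%.3g, T1/2 %.4g+/-%.3g min, k' %.3g+/-%.3g, alpha %.4g+/-%.3g %%\n",
    object@label, object@n, object@mean["Dstar"], object@sd["Dstar"],
    object@mean["Thalf"], object@sd["Thalf"], object@mean["kprime"],
    object@sd["kprime"], object@mean["alpha"], object@sd["alpha"]))
})

setMethod("show", "ParamMap", function(object) {
  v <- object@values
  cat(sprintf(
    "ParamMap (%s): %d x %d x %d voxels, %d unmasked (%.1f%%), median %.4g\n",
    object@units, dim(v)[1], dim(v)[2], dim(v)[3], sum(!is.na(v)),
    100 * mean(!is.na(v)), stats::median(v, na.rm = TRUE)))
})

#' Coerce an ECSResult to a one-row data.frame
#'
#' @param x an [ECSResult]
#' @param row.names,optional,... ignored
#' @return one-row data.frame with internal-unit and reporting-scale columns
#' @export
as.data.frame.ECSResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(Dstar = x@Dstar, DstarReported = x@DstarReported,
             Dx = x@Dx, Dy = x@Dy, Dz = x@Dz,
             k = x@k, kReported = x@kReported,
             Thalf = x@Thalf, ThalfCensored = x@ThalfCensored,
             ThalfModel = x@ThalfModel,
             alphaPct = x@alphaPct, alphaClipped = x@alphaClipped,
             amplitude = x@amplitude, rss = x@rss, r2 = x@r2,
             converged = x@converged)
}

#' Coerce an ROITimecourse to a data.frame
#'
#' @param x an [ROITimecourse]
#' @param row.names,optional,... ignored
#' @export
as.data.frame.ROITimecourse <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time = x@times, enhancement = x@enhancement)
}
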