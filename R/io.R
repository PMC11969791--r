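#' @include AllClasses.R synthetic-data.R
NULL

.paramsToList <- function(p) {
  if (is.null(p)) return(NULL)
  list(Dx = p@Dx, Dy = p@Dy, Dz = p@Dz, k = p@k, alpha = p@alpha)
}

.paramsFromList <- function(x) {
  if (is.null(x)) return(NULL)
  DiffusionParams(x$Dx, x$Dy, x$Dz, k = x$k, alpha = x$alpha)
}

#' Write a tracer study to disk
#'
#' Serializes a [TracerStudy] as a study bundle: a 4D NIfTI image
#' (`signal.nii.gz`, voxel spacing in the header) plus a JSON sidecar
#' (`study.json`) carrying what NIfTI headers cannot: the exact scan times,
#' grid origin, injection protocol, signal and noise parameters and -- for
#' synthetic studies -- the ground truth. The round trip through
#' [readStudy()] is lossless.
#'
#' @param study [TracerStudy]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "TracerStudy"))
  validObject(study)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(study@signal)
  dt <- if (length(study@times) > 1L) diff(study@times)[1L] else 1
  img <- RNifti::`pixdim<-`(img, c(study@grid@voxelSize, dt))
  RNifti::writeNifti(img, file.path(dir, "signal.nii.gz"))
  sp <- study@signalParams
  sidecar <- list(
    label = study@label,
    shape = study@grid@shape,
    voxelSize = study@grid@voxelSize,
    origin = study@grid@origin,
    times = study@times,
    protocol = list(volume = study@protocol@volume,
                    concentration = study@protocol@concentration,
                    site = study@protocol@site),
    signal = list(mode = sp@mode, kappa = sp@kappa, r1 = sp@r1,
                  T10 = sp@T10, TR = sp@TR, TE = sp@TE, TI = sp@TI,
                  flipAngle = sp@flipAngle),
    noise = list(kind = study@noise@kind, sigma = study@noise@sigma,
                 seed = study@noise@seed),
    truth = .paramsToList(study@truth))
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a tracer study bundle
#'
#' Inverse of [writeStudy()]. The image and sidecar are cross-checked: a
#' mismatch between the image dimensions and the sidecar's `shape` or
#' `times` is an error naming the offending field.
#'
#' @param dir study directory containing `signal.nii.gz` and `study.json`
#' @return a [TracerStudy]
#' @export
readStudy <- function(dir) {
  imgPath <- file.path(dir, "signal.nii.gz")
  scPath <- file.path(dir, "study.json")
  if (!file.exists(scPath))
    stop("missing sidecar 'study.json' in ", dir)
  if (!file.exists(imgPath))
    stop("missing image 'signal.nii.gz' in ", dir)
  sc <- jsonlite::read_json(scPath, simplifyVector = TRUE)
  img <- RNifti::readNifti(imgPath)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (!all(dim(arr)[1:3] == sc$shape))
    stop("field 'shape': sidecar grid does not match the image dimensions")
  if (dim(arr)[4L] != length(sc$times))
    stop("field 'times': sidecar time count does not match the image")
  grid <- new("Grid3D", shape = as.integer(sc$shape),
              voxelSize = as.numeric(sc$voxelSize),
              origin = as.numeric(sc$origin))
  sp <- do.call(SignalParams, sc$signal)
  noise <- NoiseModel(sc$noise$kind,
                      sigma = if (is.null(sc$noise$sigma)) NA_real_ else
                        as.numeric(sc$noise$sigma),
                      seed = if (is.null(sc$noise$seed)) NA_integer_ else
                        as.integer(sc$noise$seed))
  new("TracerStudy", signal = arr, grid = grid,
      times = as.numeric(sc$times),
      protocol = InjectionProtocol(sc$protocol$volume,
                                   sc$protocol$concentration,
                                   as.numeric(sc$protocol$site)),
      signalParams = sp, noise = noise,
      truth = .paramsFromList(sc$truth),
      label = as.character(sc$label))
}

#' Write a concentration field as 4D NIfTI
#'
#' One volume per time point; voxel spacing in the header, exact times in a
#' JSON sidecar next to the image.
#'
#' @param field [ConcentrationField]
#' @param path output path (`.nii.gz`)
#' @return `path`, invisibly
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "ConcentrationField"))
  img <- RNifti::asNifti(field@values)
  dt <- if (length(field@times) > 1L) diff(field@times)[1L] else 1
  img <- RNifti::`pixdim<-`(img, c(field@grid@voxelSize, dt))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(times = field@times, voxelSize = field@grid@voxelSize,
         origin = field@grid@origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a parameter map as NIfTI
#'
#' @param map [ParamMap]
#' @param path output path (`.nii.gz`); masked voxels are stored as NaN
#' @return `path`, invisibly
#' @export
writeMap <- function(map, path) {
  stopifnot(is(map, "ParamMap"))
  img <- RNifti::asNifti(map@values)
  img <- RNifti::`pixdim<-`(img, map@grid@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write or read a simulated cohort
#'
#' A cohort ([makeGroupDataset()]) is laid out as one study bundle per
#' animal plus a `truth.csv` ground-truth table at the top level. The CSV
#' round-trips losslessly (full double precision).
#'
#' @param cohort list with `studies` and `truth`
#' @param dir cohort directory
#' @return `dir` (write) or the cohort list (read), invisibly for write
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in cohort$studies)
    writeStudy(st, file.path(dir, st@label))
  if (!is.null(cohort$truth))
    utils::write.csv(format(cohort$truth, digits = 17, trim = TRUE),
                     file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  dirs <- list.dirs(dir, recursive = FALSE)
  studies <- lapply(dirs, readStudy)
  truthPath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthPath))
    utils::read.csv(truthPath, stringsAsFactors = FALSE) else NULL
  if (!is.null(truth))
    for (cc in c("Dstar", "Thalf", "alpha", "D", "k", "alphaFrac"))
      if (cc %in% names(truth)) truth[[cc]] <- as.numeric(truth[[cc]])
  list(studies = studies, truth = truth)
}

#' Read a group-summary CSV
#'
#' Expects columns `label`, `mean`, `sd`, `n` (UTF-8, comma-separated,
#' header row, '.' decimal), validated on read.
#'
#' @param path CSV path
#' @return validated summary data.frame
#' @export
readGroupSummaries <- function(path) {
  .checkSummary(utils::read.csv(path, stringsAsFactors = FALSE))
}
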