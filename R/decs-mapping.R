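#' @include AllClasses.R estimation.R
NULL

#' Rendering configuration for parameter maps
#'
#' Follows the Decs-mapping display convention: the lowest map value is
#' rendered blue and the highest red, with a perceptually ordered ramp in
#' between (the exact ramp is configurable; only the endpoints are fixed by
#' convention).
#'
#' @slot lowColor,highColor colormap endpoints
#' @slot nLevels number of contour levels
#' @slot levels explicit contour levels (increasing) or NULL for automatic
#' @slot width,height output raster size in pixels
#' @slot theta,phi viewing angles for the 3D wireframe (degrees)
#' @export
setClass("RenderConfig",
  slots = c(lowColor = "character", highColor = "character",
            nLevels = "integer", levels = "NumericOrNULL",
            width = "integer", height = "integer",
            theta = "numeric", phi = "numeric"))

setValidity("RenderConfig", function(object) {
  msg <- character()
  if (!is.null(object@levels) && length(object@levels) > 1L &&
      any(diff(object@levels) <= 0))
    msg <- c(msg, "'levels' must be increasing")
  if (object@width < 50L || object@height < 50L)
    msg <- c(msg, "raster size must be at least 50 x 50")
  if (length(msg)) msg else TRUE
})

#' @param lowColor,highColor colormap endpoints (blue and red by
#'   convention)
#' @param nLevels number of contour levels
#' @param levels explicit increasing contour levels, or NULL
#' @param width,height raster size (pixels)
#' @param theta,phi 3D viewing angles (degrees)
#' @rdname RenderConfig-class
#' @export
RenderConfig <- function(lowColor = "blue", highColor = "red",
                         nLevels = 12L, levels = NULL, width = 600L,
                         height = 600L, theta = 30, phi = 30) {
  new("RenderConfig", lowColor = lowColor, highColor = highColor,
      nLevels = as.integer(nLevels), levels = levels,
      width = as.integer(width), height = as.integer(height),
      theta = theta, phi = phi)
}

.rampColors <- function(cfg, n) {
  grDevices::colorRampPalette(c(cfg@lowColor, "cyan", "yellow",
                                cfg@highColor))(n)
}

#' Voxelwise local diffusion-parameter (Decs/ADCe) map
#'
#' Computes the local effective diffusion coefficient at every informative
#' voxel by a windowed fit of the point-source model: for each voxel, the
#' amplitudes of all voxels in a cubic window of radius `windowRadius`
#' across all post-injection times are fitted for (local D, amplitude) with
#' the clearance rate held at a study-level value. Voxels failing the
#' informative criterion (peak enhancement above `snrThreshold` baseline
#' noise SDs, or above a relative floor for noiseless data) are masked
#' (NA), never zero-filled.
#'
#' @param study [TracerStudy]
#' @param windowRadius window radius in voxels (window edge 2r+1 >= 3)
#' @param k study-level clearance rate; NULL fits it first via
#'   [fitDiffusionModel()]
#' @param voxels optional logical mask restricting which voxels are
#'   computed (intersected with the informative mask); useful to map a
#'   slice or subvolume
#' @param snrThreshold informative-voxel threshold
#' @return a [ParamMap] of local D (mm^2/min)
#' @export
computeLocalDMap <- function(study, windowRadius = 2L, k = NULL,
                             voxels = NULL, snrThreshold = 3) {
  stopifnot(is(study, "TracerStudy"))
  validObject(study)
  windowRadius <- as.integer(windowRadius)
  if (2L * windowRadius + 1L < 3L)
    stop("window must span at least 3 voxels (windowRadius >= 1)")
  tt <- study@times[-1L]
  if (length(tt) < 3L)
    stop("need at least 3 post-injection time points")
  d <- dim(study@signal)
  sigma <- .estimateNoiseSD(study)
  rician <- study@noise@kind == "rician" && sigma > 0
  if (rician) {
    E <- .ricianCorrect(study@signal[, , , -1L, drop = FALSE], sigma)
  } else {
    E <- study@signal[, , , -1L, drop = FALSE] -
      array(study@signal[, , , 1L], c(d[1:3], length(tt)))
  }
  globalFit <- NULL
  if (is.null(k)) {
    globalFit <- fitDiffusionModel(study)
    k <- globalFit@k
  }
  Dinit <- if (is.null(globalFit)) 0.02 else globalFit@Dstar
  peakE <- apply(E, 1:3, max)
  thr <- if (sigma > 0) snrThreshold * sigma else 1e-8 * max(peakE)
  mask <- peakE > thr
  if (!is.null(voxels)) {
    stopifnot(all(dim(voxels) == d[1:3]))
    mask <- mask & as.logical(voxels)
  }
  idx <- which(mask)
  vals <- array(NA_real_, d[1:3])
  if (!length(idx)) return(new("ParamMap", values = vals,
                               grid = study@grid, units = "mm^2/min"))
  coords <- lapply(1:3, function(a)
    axisCoords(study@grid, a) - study@protocol@site[a])
  off <- -windowRadius:windowRadius
  iv <- arrayInd(idx, d[1:3])
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100L)
  for (m in seq_along(idx)) {
    ci <- iv[m, ]
    wi <- lapply(1:3, function(a) {
      w <- ci[a] + off
      w[w >= 1L & w <= d[a]]
    })
    win <- as.matrix(expand.grid(wi[[1L]], wi[[2L]], wi[[3L]]))
    d2 <- cbind(coords[[1L]][win[, 1L]]^2, coords[[2L]][win[, 2L]]^2,
                coords[[3L]][win[, 3L]]^2)
    y <- matrix(0, nrow(win), length(tt))
    lin <- win[, 1L] + (win[, 2L] - 1L) * d[1L] +
      (win[, 3L] - 1L) * d[1L] * d[2L]
    for (j in seq_along(tt)) y[, j] <- E[, , , j][lin]
    yv <- as.vector(y)
    g1 <- as.vector(.kernelPredict(d2, tt, Dinit, Dinit, Dinit, k, 1))
    A0 <- max(sum(yv * g1) / sum(g1^2), 1e-8)
    fit <- minpack.lm::nls.lm(
      par = c(D = Dinit, A = A0), lower = c(1e-4, 1e-10),
      upper = c(1, Inf),
      fn = function(p) as.vector(
        .kernelPredict(d2, tt, p[1L], p[1L], p[1L], k, p[2L])) - yv,
      control = ctrl)
    vals[idx[m]] <- fit$par[[1L]]
  }
  new("ParamMap", values = vals, grid = study@grid, units = "mm^2/min")
}

.sliceValues <- function(map, slice) {
  d <- dim(map@values)
  if (is.null(slice)) slice <- (d[3L] + 1L) %/% 2L
  stopifnot(slice >= 1L, slice <= d[3L])
  list(z = map@values[, , slice], slice = slice)
}

#' Render a 2D contour view of a parameter map
#'
#' Draws the selected axial slice as a filled color image (map minimum in
#' the low-endpoint color, maximum in the high-endpoint color) with contour
#' lines, optionally superimposed on a grayscale underlay (e.g. the
#' original MR image). The render is a pure function of (map, underlay,
#' config): repeated calls produce byte-identical files.
#'
#' @param map [ParamMap]
#' @param file output PNG path
#' @param underlay optional 2D matrix co-registered with the slice
#' @param slice z index (default: middle slice)
#' @param cfg [RenderConfig]
#' @return the file path, invisibly
#' @export
renderContour2D <- function(map, file, underlay = NULL, slice = NULL,
                            cfg = RenderConfig()) {
  stopifnot(is(map, "ParamMap"), is(cfg, "RenderConfig"))
  validObject(cfg)
  sl <- .sliceValues(map, slice)
  z <- sl$z
  if (all(is.na(z))) stop("selected slice is fully masked")
  if (!is.null(underlay) && !all(dim(underlay) == dim(z)))
    stop("underlay dimensions do not match the map slice")
  xs <- axisCoords(map@grid, 1L)
  ys <- axisCoords(map@grid, 2L)
  rng <- range(z, na.rm = TRUE)
  grDevices::png(file, width = cfg@width, height = cfg@height)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  if (diff(rng) <= 1e-10 * max(abs(rng), 1e-300)) {
    graphics::image(xs, ys, matrix(1, nrow(z), ncol(z)),
                    col = cfg@lowColor, xlab = "x (mm)", ylab = "y (mm)",
                    main = sprintf("Decs map, slice %d", sl$slice))
  } else {
    if (!is.null(underlay))
      graphics::image(xs, ys, underlay,
                      col = grDevices::gray.colors(64, 0, 1),
                      xlab = "x (mm)", ylab = "y (mm)",
                      main = sprintf("Decs map, slice %d", sl$slice))
    levels <- if (is.null(cfg@levels))
      pretty(rng, cfg@nLevels) else cfg@levels
    levels <- levels[levels > rng[1L] & levels < rng[2L]]
    breaks <- unique(sort(c(rng[1L], levels, rng[2L])))
    cols <- .rampColors(cfg, length(breaks) - 1L)
    graphics::image(xs, ys, z, col = cols, breaks = breaks,
                    add = !is.null(underlay),
                    xlab = "x (mm)", ylab = "y (mm)",
                    main = if (is.null(underlay))
                      sprintf("Decs map, slice %d", sl$slice) else "")
    if (length(levels))
      graphics::contour(xs, ys, z, levels = levels, add = TRUE,
                        col = "black", lwd = 0.5)
  }
  invisible(file)
}

#' Render a 3D wireframe view of a parameter map slice
#'
#' The Decs-mapping wireframe: surface height encodes the local diffusion
#' parameter of the selected slice (low values blue, high red), with the 2D
#' contour plot projected onto the bottom plane. Deterministic: identical
#' inputs give byte-identical files.
#'
#' @param map [ParamMap]
#' @param file output PNG path
#' @param slice z index (default: middle slice)
#' @param cfg [RenderConfig]
#' @return the file path, invisibly
#' @export
renderWireframe3D <- function(map, file, slice = NULL,
                              cfg = RenderConfig()) {
  stopifnot(is(map, "ParamMap"), is(cfg, "RenderConfig"))
  validObject(cfg)
  sl <- .sliceValues(map, slice)
  z <- sl$z
  if (all(is.na(z))) stop("selected slice is fully masked")
  xs <- axisCoords(map@grid, 1L)
  ys <- axisCoords(map@grid, 2L)
  rng <- range(z, na.rm = TRUE)
  zfloor <- rng[1L] - 0.25 * max(rng[2L] - rng[1L], abs(rng[1L]), 1e-12)
  grDevices::png(file, width = cfg@width, height = cfg@height)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  ## facet colors by mean height, low -> blue, high -> red
  nc <- 64L
  pal <- .rampColors(cfg, nc)
  zf <- (z[-1L, -1L] + z[-1L, -ncol(z)] + z[-nrow(z), -1L] +
         z[-nrow(z), -ncol(z)]) / 4
  colIdx <- if (diff(rng) <= 1e-10 * max(abs(rng), 1e-300))
    rep(1L, length(zf)) else
    pmin(nc, pmax(1L, 1L + floor((zf - rng[1L]) / (rng[2L] - rng[1L]) *
                                 (nc - 1L))))
  facetCol <- matrix(pal[colIdx], nrow(zf), ncol(zf))
  facetCol[is.na(zf)] <- NA
  pmat <- graphics::persp(xs, ys, z, zlim = c(zfloor, rng[2L]),
                          theta = cfg@theta, phi = cfg@phi,
                          col = facetCol, border = "grey30",
                          xlab = "x (mm)", ylab = "y (mm)",
                          zlab = "Decs", ticktype = "detailed",
                          main = sprintf("Decs wireframe, slice %d",
                                         sl$slice))
  if (diff(rng) > 1e-10 * max(abs(rng), 1e-300)) {
    levels <- if (is.null(cfg@levels))
      pretty(rng, cfg@nLevels) else cfg@levels
    levels <- levels[levels > rng[1L] & levels < rng[2L]]
    z0 <- z; z0[is.na(z0)] <- rng[1L]
    cl <- if (length(levels))
      grDevices::contourLines(xs, ys, z0, levels = levels) else list()
    for (li in cl) {
      idx <- pmin(nc, pmax(1L, 1L + floor((li$level - rng[1L]) /
                                          (rng[2L] - rng[1L]) * (nc - 1L))))
      pts <- grDevices::trans3d(li$x, li$y, zfloor, pmat)
      graphics::lines(pts, col = pal[idx], lwd = 1)
    }
  }
  invisible(file)
}
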