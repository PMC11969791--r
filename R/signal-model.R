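#' @include AllClasses.R
NULL

## Spoiled gradient-echo steady-state magnitude signal for longitudinal
## relaxation rate R1 (1/s): S = sin(a) (1 - E1) / (1 - cos(a) E1),
## E1 = exp(-TR * R1). Monotone increasing in R1 for flip angles < 90 deg.
.spgrSignal <- function(R1, p) {
  a <- p@flipAngle * pi / 180
  E1 <- exp(-p@TR * R1)
  sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Map tracer concentration to relative signal enhancement
#'
#' A paramagnetic tracer shortens the longitudinal relaxation time of tissue
#' water, raising the T1-weighted signal. In `"linear"` mode (the default,
#' appropriate at small concentrations) the relative enhancement is
#' \eqn{E = \kappa C}. In `"relaxivity"` mode the relaxation rate is
#' \eqn{1/T_1 = 1/T_{10} + r_1 C} and the enhancement is computed from the
#' spoiled gradient-echo steady-state signal,
#' \eqn{E = S(C)/S(0) - 1}, a monotone saturating map.
#'
#' @param C concentration(s), mM, non-negative
#' @param p [SignalParams]
#' @return relative enhancement (dimensionless), 0 at C = 0
#' @examples
#' concentrationToEnhancement(2, SignalParams(kappa = 0.5))  # 1.0
#' @export
concentrationToEnhancement <- function(C, p = SignalParams()) {
  stopifnot(is(p, "SignalParams"))
  if (any(C < 0)) stop("concentrations must be non-negative")
  if (p@mode == "linear") {
    p@kappa * C
  } else {
    S0 <- .spgrSignal(1 / p@T10, p)
    .spgrSignal(1 / p@T10 + p@r1 * C, p) / S0 - 1
  }
}

#' Invert signal enhancement to concentration
#'
#' Inverse of [concentrationToEnhancement()]. Linear mode is exact; in
#' relaxivity mode the monotone signal equation is solved numerically
#' (relative tolerance ~1e-12). Enhancements at or above the saturation
#' asymptote of the relaxivity curve are an error.
#'
#' @param E relative enhancement(s), non-negative
#' @param p [SignalParams]
#' @return concentration(s), mM
#' @export
enhancementToConcentration <- function(E, p = SignalParams()) {
  stopifnot(is(p, "SignalParams"))
  if (any(E < 0)) stop("enhancements must be non-negative")
  if (p@mode == "linear") return(E / p@kappa)
  a <- p@flipAngle * pi / 180
  S0 <- .spgrSignal(1 / p@T10, p)
  Emax <- sin(a) / S0 - 1          # R1 -> Inf limit
  if (any(E >= Emax))
    stop(sprintf(
      "enhancement %.4g is at/above the saturation asymptote %.4g",
      max(E), Emax))
  vapply(E, function(e) {
    if (e == 0) return(0)
    target <- (1 + e) * S0
    ## solve for E1 in sin(a)(1 - E1)/(1 - cos(a) E1) = target, then R1, C
    E1 <- (sin(a) - target) / (sin(a) - target * cos(a))
    R1 <- -log(E1) / p@TR
    (R1 - 1 / p@T10) / p@r1
  }, numeric(1))
}

#' Add magnitude-MRI noise to an image
#'
#' Rician noise is the magnitude-image noise convention:
#' \eqn{S_{out} = \sqrt{(S + n_1)^2 + n_2^2}} with independent
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)}. At zero signal this reduces to a
#' Rayleigh distribution with mean \eqn{\sigma\sqrt{\pi/2}}; at
#' signal-to-noise ratios above ~10 it is close to Gaussian. A seed in the
#' [NoiseModel] makes the draw reproducible (the caller's RNG state is
#' preserved).
#'
#' @param image numeric array, finite and non-negative
#' @param nm [NoiseModel]
#' @return array of the same shape
#' @export
addNoise <- function(image, nm) {
  stopifnot(is(nm, "NoiseModel"))
  validObject(nm)
  if (any(!is.finite(image))) stop("image must be finite")
  if (nm@kind == "none") return(image)
  if (is.na(nm@sigma))
    stop("noise sigma is NA; resolve it (e.g. via sigmaForPeakSNR) first")
  if (nm@sigma == 0) return(image)
  if (!is.na(nm@seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(nm@seed)
  }
  n <- length(image)
  if (nm@kind == "gaussian") {
    out <- image + stats::rnorm(n, 0, nm@sigma)
  } else {
    n1 <- stats::rnorm(n, 0, nm@sigma)
    n2 <- stats::rnorm(n, 0, nm@sigma)
    out <- sqrt((image + n1)^2 + n2^2)
  }
  dim(out) <- dim(image)
  out
}

#' Noise SD for a target peak signal-to-noise ratio
#'
#' @param signal noiseless signal array
#' @param peakSNR target ratio of peak signal to noise SD
#' @return sigma = max(signal) / peakSNR
#' @export
sigmaForPeakSNR <- function(signal, peakSNR) {
  stopifnot(peakSNR > 0)
  max(signal) / peakSNR
}
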