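#' @include AllClasses.R
NULL

## Validate a (label, mean, sd, n) summary table.
.checkSummary <- function(groups) {
  if (!is.data.frame(groups) ||
      !all(c("label", "mean", "sd", "n") %in% names(groups)))
    stop("group summaries must be a data.frame with label, mean, sd, n")
  if (any(groups$sd < 0)) stop("SDs must be >= 0")
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  groups
}

#' Construct a group-summary table
#'
#' The summary-statistics representation of a study table: one row per
#' group with its mean, SD and sample size, the form in which animal-study
#' results are printed.
#'
#' @param label group labels
#' @param mean,sd group means and SDs
#' @param n group sizes (>= 2)
#' @return validated data.frame
#' @export
groupSummary <- function(label, mean, sd, n) {
  .checkSummary(data.frame(label = label, mean = mean, sd = sd, n = n))
}

#' One-way ANOVA from summary statistics
#'
#' Computes the one-way fixed-effects ANOVA exactly as it would come out of
#' raw data having precisely the given group means, SDs and sizes: the
#' between-group sum of squares from the means
#' (\eqn{SS_B = \sum_i n_i (\bar x_i - \bar x)^2}) and the within-group sum
#' of squares from the SDs (\eqn{SS_W = \sum_i (n_i - 1) s_i^2}).
#'
#' @param groups data.frame with columns label, mean, sd, n (>= 2 rows)
#' @return data.frame with `F`, `df1`, `df2`, `p`
#' @examples
#' g <- groupSummary(c("a", "b"), c(1, 2), c(0.5, 0.5), c(6, 6))
#' anovaFromSummary(g)
#' @export
anovaFromSummary <- function(groups) {
  groups <- .checkSummary(groups)
  g <- nrow(groups)
  if (g < 2L) stop("need at least two groups")
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  df1 <- g - 1L
  df2 <- N - g
  msb <- ssb / df1
  msw <- ssw / df2
  Fstat <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  data.frame(F = Fstat, df1 = df1, df2 = df2, p = p)
}

#' Pooled-variance pairwise contrasts after a one-way ANOVA
#'
#' The ANOVA-consistent post-hoc comparison: each pairwise contrast uses
#' the pooled within-group mean square of the omnibus ANOVA and its full
#' error degrees of freedom,
#' \eqn{t = (\bar x_i - \bar x_j) / \sqrt{MS_W (1/n_i + 1/n_j)}} on
#' \eqn{\sum_k (n_k - 1)} df, with two-sided p-values adjusted across the
#' declared family by the Benjamini--Hochberg step-up procedure.
#'
#' @param groups data.frame with columns label, mean, sd, n
#' @param pairs 2-column matrix (or list of length-2 vectors) of group row
#'   indices; default all pairs. `i = j` is an error.
#' @return data.frame with contrast labels, `t`, `df`, `p`, `p_adjusted`
#' @examples
#' g <- groupSummary(c("sham", "pd"), c(3.09, 4.21), c(0.08, 0.13), 6)
#' posthocPooled(g)
#' @export
posthocPooled <- function(groups, pairs = NULL) {
  groups <- .checkSummary(groups)
  g <- nrow(groups)
  if (g < 2L) stop("need at least two groups")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(g, 2L))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a contrast of a group with itself (i = j) is not defined")
  if (any(pairs < 1L) || any(pairs > g)) stop("pair index out of range")
  df <- sum(groups$n - 1L)
  msw <- sum((groups$n - 1) * groups$sd^2) / df
  res <- apply(pairs, 1L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(msw * (1 / groups$n[i] + 1 / groups$n[j]))
    t <- if (se == 0) {
      if (groups$mean[i] == groups$mean[j]) 0 else
        Inf * sign(groups$mean[i] - groups$mean[j])
    } else (groups$mean[i] - groups$mean[j]) / se
    c(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  })
  out <- data.frame(
    groupA = groups$label[pairs[, 1L]],
    groupB = groups$label[pairs[, 2L]],
    t = res["t", ], df = df, p = res["p", ],
    row.names = NULL)
  out$p_adjusted <- fdrBH(out$p)
  out
}

#' Welch two-sample test from summary statistics
#'
#' Robustness alternative to the pooled contrast: does not assume equal
#' group variances. Uses the Welch statistic with Satterthwaite degrees of
#' freedom. With equal n and equal SDs it coincides with the pooled
#' two-sample t test.
#'
#' @param a,b one-row data.frames (or named lists) with mean, sd, n
#' @return data.frame with `t`, `df`, `p`
#' @export
welchTFromSummary <- function(a, b) {
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    t <- if (a$mean == b$mean) 0 else Inf * sign(a$mean - b$mean)
    return(data.frame(t = t, df = a$n + b$n - 2,
                      p = if (t == 0) 1 else 0))
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  data.frame(t = t, df = df,
             p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control with enforced monotonicity, as implemented in
#' [stats::p.adjust()] (method `"BH"`); input order is preserved.
#'
#' @param pvals p-values in [0, 1]
#' @return adjusted p-values, same order
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
fdrBH <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance
#' @return data.frame with `r`, `p`, `n`
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Reconstruct raw data matching printed summary statistics exactly
#'
#' Affine-transforms a zero-mean, unit-SD n-vector to the requested mean
#' and SD exactly (sample SD, denominator n - 1). Any raw dataset built
#' this way reproduces a summary-statistics ANOVA exactly, which is the
#' basis of the oracle equivalence between the two pathways.
#'
#' @param mean,sd target sample moments
#' @param n sample size (>= 2)
#' @return numeric vector of length n with exactly these moments
#' @examples
#' x <- momentMatchedSample(3.09, 0.08, 6)
#' c(mean(x), sd(x))
#' @export
momentMatchedSample <- function(mean, sd, n) {
  if (n < 2L) stop("need n >= 2")
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
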