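refDstar <- function()
  groupSummary(c("sham", "pd", "nst", "st"),
               c(3.09, 4.21, 4.12, 3.74),
               c(0.08, 0.13, 0.19, 0.27), 6L)

test_that("summary ANOVA handles identical groups and scaling laws", {
  g <- groupSummary(c("a", "b", "c"), c(2, 2, 2), c(0.5, 0.5, 0.5), 6L)
  av <- anovaFromSummary(g)
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)
  ## doubling all SDs quarters F
  g1 <- groupSummary(c("a", "b"), c(1, 2), c(0.4, 0.6), 6L)
  g2 <- g1; g2$sd <- 2 * g1$sd
  expect_equal(anovaFromSummary(g2)$F, anovaFromSummary(g1)$F / 4,
               tolerance = 1e-12)
  expect_error(anovaFromSummary(groupSummary("a", 1, 1, 6)), "two groups")
  expect_error(groupSummary(c("a", "b"), c(1, 2), c(1, 1), c(1, 6)),
               "n >= 2")
})

test_that("reference D* rows give F ~ 47.0 on (3, 20) df", {
  av <- anovaFromSummary(refDstar())
  expect_equal(av$df1, 3)
  expect_equal(av$df2, 20)
  expect_equal(av$F, 47.0, tolerance = 0.01)
})

test_that("summary ANOVA equals raw-data ANOVA on moment-matched data", {
  tables <- list(
    refDstar(),
    groupSummary(c("sham", "pd", "st"), c(0.27, 2.31, 0.75),
                 c(0.14, 0.82, 0.36), 6L),
    groupSummary(c("g1", "g2"), c(10, 10.5), c(1.1, 0.8), c(4L, 9L)))
  for (g in tables) {
    raw <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      data.frame(group = g$label[i],
                 y = momentMatchedSample(g$mean[i], g$sd[i], g$n[i]))))
    fit <- stats::aov(y ~ group, raw)
    tab <- summary(fit)[[1]]
    av <- anovaFromSummary(g)
    expect_equal(av$F, tab[["F value"]][1], tolerance = 1e-10)
    expect_equal(av$p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("moment-matched samples reproduce the printed moments exactly", {
  x <- momentMatchedSample(3.09, 0.08, 6)
  expect_equal(mean(x), 3.09, tolerance = 1e-14)
  expect_equal(sd(x), 0.08, tolerance = 1e-14)
  expect_error(momentMatchedSample(1, 1, 1), "n >= 2")
})

test_that("pooled post-hoc contrasts use the omnibus MSW and its df", {
  g <- refDstar()
  ph <- posthocPooled(g, pairs = list(c(2, 1)))  # pd vs sham
  expect_equal(ph$df, 20)
  expect_equal(ph$t, 10.67, tolerance = 0.005)
  expect_lt(ph$p, 1e-4)
  ## identical groups give p = 1
  ge <- groupSummary(c("a", "b"), c(1, 1), c(0.3, 0.3), 6L)
  expect_equal(posthocPooled(ge)$p, 1)
  expect_error(posthocPooled(g, pairs = list(c(2, 2))), "i = j")
  ## BH adjustment never decreases a p-value
  phAll <- posthocPooled(g)
  expect_true(all(phAll$p_adjusted >= phAll$p))
})

test_that("Welch test from summaries matches pooled t under equal n and SD", {
  a <- data.frame(mean = 1.0, sd = 0.5, n = 6)
  b <- data.frame(mean = 1.8, sd = 0.5, n = 6)
  w <- welchTFromSummary(a, b)
  g <- groupSummary(c("a", "b"), c(1.0, 1.8), c(0.5, 0.5), 6L)
  ph <- posthocPooled(g)
  expect_equal(abs(w$t), abs(ph$t), tolerance = 1e-12)
  expect_equal(w$df, 10)
  ## equal summaries: t = 0, p = 1
  w0 <- welchTFromSummary(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  ## reference glutamate rows: |t| ~ 6.0
  wg <- welchTFromSummary(data.frame(mean = 2.31, sd = 0.82, n = 6),
                          data.frame(mean = 0.27, sd = 0.14, n = 6))
  expect_equal(wg$t, 6.0, tolerance = 0.01)
})

test_that("BH adjustment matches hand-computed values and its properties", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrBH(0.2), 0.2)                 # single p unchanged
  p <- c(0.001, 0.02, 0.04, 0.8)
  adj <- fdrBH(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  ## order-preserving
  expect_equal(order(adj), order(p))
  ## monotone in the inputs
  adj2 <- fdrBH(p / 2)
  expect_true(all(adj2 <= adj))
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation matches known values and is affine-invariant", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCor(x, 2 * x)$r, 1)
  expect_equal(pearsonCor(x, -x)$r, -1)
  set.seed(8)
  y <- x + rnorm(5)
  r1 <- pearsonCor(x, y)
  r2 <- pearsonCor(10 + 3 * x, y)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(pearsonCor(x, rep(1, 5)), "variance")
  expect_error(pearsonCor(x[1:2], x[1:2] * 2), "at least 3")
})
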