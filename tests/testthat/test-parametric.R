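test_that("t-test variants reproduce hand calculations and attach d", {
  r <- tTestES(c(1, 2, 3), c(3, 4, 5), variant = "student")
  expect_equal(unname(r@statistic), -2.449490, tolerance = 1e-6)
  expect_equal(unname(r@parameter), 4)
  expect_equal(pValue(r), 0.0705, tolerance = 1e-3)
  expect_equal(effectValue(effect(r)), 2)

  x <- c(1, 3, 7, 2)
  r0 <- tTestES(x, x)
  expect_equal(unname(r0@statistic), 0)
  expect_equal(pValue(r0), 1)

  expect_error(tTestES(rep(2, 4), rep(2, 4)), "pooled variance")
})

test_that("two-way ANOVA decomposes a noise-free balanced toy exactly", {
  # factor A shifts by 2, factor B by 1, no interaction, no residual
  a <- factor(rep(c("a1", "a2"), each = 4))
  b <- factor(rep(c("b1", "b2"), 4))
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  res <- suppressWarnings(twoWayAnova(y, a, b))
  expect_equal(effectValue(effect(res$A)), 0.8)
  expect_equal(effectValue(effect(res$B)), 0.2)
  expect_lt(pValue(res$A), pValue(res$B))
})

test_that("eta squared over all effects plus residual sums to one", {
  set.seed(21)
  a <- gl(2, 12); b <- gl(3, 4, 24)
  y <- rnorm(24) + as.numeric(a)
  res <- twoWayAnova(y, a, b)
  etas <- vapply(res, function(r) effectValue(effect(r)), 0)
  resid <- 1 - sum(etas)
  expect_gte(resid, 0)
  ssTot <- res[[1]]@details$ss_total
  ssRes <- ssTot - sum(vapply(res, function(r) r@details$ss, 0))
  expect_equal(resid, ssRes / ssTot, tolerance = 1e-10)
})

test_that("a factor with identical cell means carries no variance", {
  a <- gl(2, 8); b <- gl(2, 4, 16)
  y <- c(rep(1, 8), rep(3, 8)) + rep(c(0.1, -0.1), 8)  # B-balanced wiggle
  res <- twoWayAnova(y, a, b, interaction = FALSE)
  expect_equal(effectValue(effect(res$B)), 0, tolerance = 1e-12)
})

test_that("the interaction term requires filled design cells", {
  a <- factor(c("x", "x", "y", "y"))
  b <- factor(c("u", "u", "u", "u"))
  expect_error(twoWayAnova(rnorm(4), a, b), "two levels")
  a2 <- factor(c("x", "x", "y", "y"))
  b2 <- factor(c("u", "v", "u", "u"))
  expect_error(twoWayAnova(rnorm(4), a2, b2, interaction = TRUE),
               "empty design cells")
})

test_that("crossover ANOVA finds a treatment effect that reduces episodes", {
  # AB/BA crossover, n = 25 per sequence group; treatment lowers the
  # Poisson episode rate from 1.0 to 0.4
  set.seed(31)
  hits <- 0
  nrep <- 120
  for (i in seq_len(nrep)) {
    n <- 25
    subj <- factor(rep(seq_len(2 * n), each = 2))
    period <- factor(rep(c(1, 2), 2 * n))
    seqgrp <- rep(c("AB", "BA"), each = 2 * n)
    treated <- ifelse(seqgrp == "AB", period == 1, period == 2)
    yv <- rpois(4 * n, lambda = ifelse(treated, 0.4, 1.0))
    r <- crossoverAnova(yv, subj, period, factor(treated))
    if (pValue(r) < 0.05) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.8)
})

test_that("crossover ANOVA is calibrated under the null and degenerates", {
  set.seed(32)
  rej <- 0
  nrep <- 400
  for (i in seq_len(nrep)) {
    n <- 20
    subj <- factor(rep(seq_len(2 * n), each = 2))
    period <- factor(rep(c(1, 2), 2 * n))
    treated <- factor(rep(c(TRUE, FALSE, FALSE, TRUE), n))
    yv <- rpois(4 * n, lambda = 1)
    if (pValue(crossoverAnova(yv, subj, period, treated)) < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / nrep, 0.02)
  expect_lt(rej / nrep, 0.09)

  # identical counts in both periods: no variance at all
  subj <- factor(rep(1:10, each = 2)); period <- factor(rep(1:2, 10))
  treated <- factor(rep(c(TRUE, FALSE), 10))
  r <- crossoverAnova(rep(3, 20), subj, period, treated)
  expect_equal(effectValue(effect(r)), 0)

  # a subject missing a period is excluded with a warning
  expect_warning(
    crossoverAnova(rpois(19, 1), factor(c(rep(1:9, each = 2), 10)),
                   factor(c(rep(1:2, 9), 1)),
                   factor(c(rep(c(TRUE, FALSE), 9), TRUE))),
    "missing a period")
})

test_that("Kruskal-Wallis H matches hand rank arithmetic", {
  r <- kruskalWallisH(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r@statistic), 4.571429, tolerance = 1e-6)
  # three identical groups: every rank sum equal, H = 0
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r0 <- kruskalWallisH(g)
  expect_equal(unname(r0@statistic), 0)
  expect_equal(pValue(r0), 1)
  expect_error(kruskalWallisH(list(c(1, 1), c(1, 1))), "tied")
})

test_that("diet-style four-group comparison follows the KW + U structure", {
  set.seed(33)
  groups <- list(ctrl = rpois(12, 1.0), a = rpois(12, 1.0),
                 b = rpois(12, 1.0), dha = rpois(12, 0.15))
  kw <- kruskalWallisH(groups)
  expect_lt(pValue(kw), 0.05)
  pr <- vapply(c("a", "b", "dha"), function(g)
    pValue(mannWhitneyU(groups$ctrl, groups[[g]])), 0)
  padj <- adjustPvalues(pr, "bonferroni")
  expect_lt(padj[["dha"]], 0.05)
  expect_gt(min(padj[c("a", "b")]), 0.05)
})
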