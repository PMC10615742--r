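test_that("PCA satisfies its algebraic invariants", {
  sim <- simulateLipidomics(nLipids = 40, groupSizes = c(5, 5), seed = 71)
  pc <- pcaLipids(sim$table)
  L <- ordLoadings(pc)
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  ev <- explainedVariance(pc)
  expect_true(all(diff(ev) <= 1e-12))
  # full reconstruction
  X <- preprocessLipids(sim$table)
  expect_equal(ordScores(pc) %*% t(L), X, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_warning(pcaLipids(sim$table, nComponents = 50), "truncating")
})

test_that("a rank-one table loads everything on PC1", {
  set.seed(70)
  t_dir <- rnorm(12)
  m <- 1000 + outer(rnorm(20), t_dir)  # one direction of variation
  dimnames(m) <- list(paste0("L", 1:20), paste0("S", 1:12))
  lt <- LipidTable(m, rep("PC", 20), rep("16:0", 20),
                   data.frame(genotype = rep(c("a", "b"), 6)))
  pc <- pcaLipids(lt, log2 = FALSE, scale = "none")
  expect_gt(explainedVariance(pc)[1], 0.999)
})

test_that("genotype-structured tables separate in PCA and clustering", {
  seps <- vapply(1:10, function(s) {
    sim <- makeEffectLipidTable(seed = 700 + s, d = 2.5)
    hc <- hierarchicalClusteringLipids(sim$table)
    k2 <- cutree(hc, 2)
    g <- SummarizedExperiment::colData(sim$table)$genotype
    length(unique(paste(k2, g))) == 2  # clusters == genotypes
  }, TRUE)
  expect_gte(mean(seps), 0.9)
})

test_that("duplicated sample blocks are recovered exactly at k = 2", {
  # two shifted blocks, each sample duplicated: k = 2 must recover the
  # blocks, and each duplicate must merge with its original at height ~0
  set.seed(72)
  base <- matrix(rnorm(30 * 6, 8, 0.2), nrow = 30)
  base[, 4:6] <- base[, 4:6] + 3
  a2 <- 2^cbind(base, base)
  dimnames(a2) <- list(paste0("L", 1:30), paste0("S", 1:12))
  blk <- rep(c(1, 1, 1, 2, 2, 2), 2)
  lt <- LipidTable(a2, rep("PC", 30), rep("16:0", 30),
                   data.frame(genotype = blk))
  hc <- hierarchicalClusteringLipids(lt, scale = "none")
  k2 <- cutree(hc, 2)
  expect_equal(length(unique(paste(k2, blk))), 2)

  # identical samples: all merge heights 0
  a3 <- a2[, rep(1, 4)]; colnames(a3) <- paste0("S", 1:4)
  lt3 <- LipidTable(a3, rep("PC", 30), rep("16:0", 30),
                    data.frame(genotype = rep(1, 4)))
  hc3 <- hierarchicalClusteringLipids(lt3, scale = "none")
  expect_equal(max(abs(hc3$height)), 0, tolerance = 1e-8)

  # Newick export parses back with the right tips
  nwk <- dendrogramNewick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("S", 1:12))
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  sim <- makeEffectLipidTable(seed = 73, groupSizes = c(10, 10), d = 3)
  op <- oplsda(sim$table, "genotype")
  y <- as.numeric(factor(
    SummarizedExperiment::colData(sim$table)$genotype))
  expect_lt(abs(cor(ordScores(op)[, 2], y)), 1e-6)
  expect_equal(componentType(op), c("predictive", "orthogonal"))
  expect_gt(op@details$R2Y, 0.5)
  # with no orthogonal component the model is single-component PLS-DA
  op0 <- oplsda(sim$table, "genotype", nOrthogonal = 0)
  X <- preprocessLipids(sim$table)
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  expect_equal(unname(ordScores(op0)[, 1]), unname(drop(X %*% w)),
               tolerance = 1e-10)
})

test_that("five planted discriminant lipids are exactly the top 1%", {
  base <- simulateLipidomics(groupSizes = c(10, 10), seed = 74)
  ids5 <- rownames(base$table)[c(7, 99, 230, 391, 452)]
  sim <- simulateLipidomics(groupSizes = c(10, 10), seed = 74,
                            effects = list(list(target = ids5, d = 6)))
  op <- oplsda(sim$table, "genotype")
  expect_equal(length(op@details$topLipids), 5)  # ceiling(0.01 * 464)
  expect_setequal(op@details$topLipids, ids5)
  expect_error(oplsda(sim$table, rep("one", 20)), "binary")
})

test_that("true labels beat permuted labels on effect-bearing data", {
  sim <- makeEffectLipidTable(seed = 75, d = 2)
  pt <- oplsdaPermutationTest(sim$table, "genotype", nPermutations = 49,
                              seed = 7)
  expect_lt(pt$pValue, 0.05)
  expect_gt(pt$observedR2Y, quantile(pt$permutedR2Y, 0.95))
})

test_that("distance analysis sees a genotype shift but no diet effect", {
  ok <- vapply(1:10, function(s) {
    sim <- makeEffectLipidTable(seed = 760 + s, groupSizes = c(8, 8),
                                d = 2)
    cd <- SummarizedExperiment::colData(sim$table)
    cd$diet <- rep(c("chow", "AIN"), 8)  # orthogonal to any signal
    SummarizedExperiment::colData(sim$table) <- cd
    res <- distanceAnova(sim$table, seed = s)
    etaG <- effectValue(effect(res$genotype))
    etaD <- effectValue(effect(res$diet))
    etaG > etaD && pValue(res$diet) > 0.05 && pValue(res$genotype) < 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  # centroid variant runs through the two-way ANOVA path
  sim <- makeEffectLipidTable(seed = 77, d = 2)
  cd <- SummarizedExperiment::colData(sim$table)
  cd$diet <- rep(c("chow", "AIN"), 8)
  SummarizedExperiment::colData(sim$table) <- cd
  resC <- distanceAnova(sim$table, method = "centroid")
  expect_s4_class(resC$genotype, "TestResult")

  # identical samples are degenerate
  m <- matrix(4, 10, 6, dimnames = list(paste0("L", 1:10),
                                        paste0("S", 1:6)))
  lt <- LipidTable(m, rep("PC", 10), rep("16:0", 10),
                   data.frame(genotype = rep(c("a", "b"), 3),
                              diet = rep(c("x", "y"), each = 3)))
  expect_error(distanceAnova(lt), "identical")
})
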