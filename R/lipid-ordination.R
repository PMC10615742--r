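#' Ordination result (PCA or OPLS-DA)
#'
#' Sample scores and lipid loadings from an unsupervised (PCA) or
#' supervised (OPLS-DA) decomposition of a preprocessed lipid table, with
#' per-component explained variance and, for OPLS-DA, the labelling of
#' predictive vs orthogonal components and the top-fraction lipid
#' selection in `details`.
#'
#' @slot scores Samples x components matrix.
#' @slot loadings Lipids x components matrix.
#' @slot explainedVariance Fraction of X variance per component.
#' @slot kind `"PCA"` or `"OPLSDA"`.
#' @slot componentType `"predictive"` / `"orthogonal"` per component
#'   (`"component"` for PCA).
#' @slot details Method-specific extras (R2Y, top lipids, weights...).
#' @export
setClass("OrdinationResult",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", kind = "character",
                 componentType = "character", details = "list"))

#' @describeIn OrdinationResult-class sample scores
#' @param x An `OrdinationResult`.
#' @export
setMethod("ordScores", "OrdinationResult", function(x) x@scores)

#' @describeIn OrdinationResult-class lipid loadings
#' @export
setMethod("ordLoadings", "OrdinationResult", function(x) x@loadings)

#' @describeIn OrdinationResult-class explained variance fractions
#' @export
setMethod("explainedVariance", "OrdinationResult",
          function(x) x@explainedVariance)

#' @describeIn OrdinationResult-class component labels
#' @export
setMethod("componentType", "OrdinationResult", function(x) x@componentType)

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("%s of %d samples x %d lipids, %d component(s)\n",
              object@kind, nrow(object@scores), nrow(object@loadings),
              ncol(object@scores)))
  ev <- object@explainedVariance
  if (length(ev))
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * ev), collapse = ", "), "\n")
})

#' Principal component analysis of a lipid table
#'
#' PCA of preprocessed (log2, centered, autoscaled by default) abundances
#' via [stats::prcomp()]. Loadings are orthonormal and explained variances
#' non-increasing; requesting more components than the matrix rank
#' truncates with a warning.
#'
#' @param table A [LipidTable-class].
#' @param nComponents Number of components to keep (default: all).
#' @param log2,scale Passed to [preprocessLipids()].
#' @return An [OrdinationResult-class] with `kind = "PCA"`.
#' @export
pcaLipids <- function(table, nComponents = NULL, log2 = TRUE,
                      scale = c("uv", "pareto", "none")) {
  X <- preprocessLipids(table, log2 = log2, scale = match.arg(scale))
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- if (is.null(nComponents)) rank else nComponents
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; truncating")
    k <- rank
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("OrdinationResult",
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explainedVariance = ev[seq_len(k)], kind = "PCA",
      componentType = rep("component", k),
      details = list(rank = rank, sdev = pc$sdev))
}

#' Hierarchical clustering of samples by lipid profile
#'
#' Agglomerative clustering of preprocessed profiles (Euclidean distance,
#' Ward linkage by default) via [stats::hclust()]. Input order is
#' preserved, so tie-breaking is deterministic in the sample order.
#'
#' @param table A [LipidTable-class].
#' @param distance A [stats::dist()] method.
#' @param linkage An [stats::hclust()] agglomeration method.
#' @param log2,scale Passed to [preprocessLipids()].
#' @return An object of class `hclust`.
#' @export
hierarchicalClusteringLipids <- function(table, distance = "euclidean",
                                         linkage = "ward.D2", log2 = TRUE,
                                         scale = c("uv", "pareto",
                                                   "none")) {
  X <- preprocessLipids(table, log2 = log2, scale = match.arg(scale))
  d <- dist(X, method = distance)
  if (any(!is.finite(d)))
    stop("non-finite distances between samples")
  hclust(d, method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` tree (e.g. from
#'   [hierarchicalClusteringLipids()]).
#' @param path Optional file path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Orthogonal PLS discriminant analysis with top-fraction selection
#'
#' O-PLS for a binary class label: variation in X orthogonal to the label
#' is removed in `nOrthogonal` deflation steps before a final
#' single-component PLS, yielding one predictive component whose loadings
#' rank the lipids by their contribution to the class difference. The top
#' `ceiling(topFraction * nLipids)` lipids by absolute predictive loading
#' are flagged (1% of 464 lipids = 5). With `nOrthogonal = 0` the model
#' reduces exactly to single-component PLS-DA. Orthogonal scores are
#' uncorrelated with the class label by construction.
#'
#' @param table A [LipidTable-class].
#' @param classes Binary grouping: a factor/vector over samples, or the
#'   name of a `colData` column.
#' @param nOrthogonal Number of orthogonal components removed.
#' @param topFraction Fraction of lipids to flag (ceiling rounding).
#' @param log2,scale Passed to [preprocessLipids()].
#' @return An [OrdinationResult-class] with `kind = "OPLSDA"`; `details`
#'   holds `topLipids`, `R2Y`, `R2X` per component and the predictive
#'   weight vector.
#' @export
oplsda <- function(table, classes = "genotype", nOrthogonal = 1,
                   topFraction = 0.01, log2 = TRUE,
                   scale = c("uv", "pareto", "none")) {
  X <- preprocessLipids(table, log2 = log2, scale = match.arg(scale))
  if (length(classes) == 1L && is.character(classes))
    classes <- SummarizedExperiment::colData(table)[[classes]]
  cl <- factor(classes)
  if (nlevels(cl) != 2L)
    stop("OPLS-DA needs a binary class label")
  if (min(table(cl)) < 3L)
    stop("need at least three samples per class")
  y <- as.numeric(cl == levels(cl)[2])
  y <- y - mean(y)
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  ssX <- sum(X^2)
  orthoScores <- orthoLoadings <- NULL
  r2xOrtho <- numeric(0)
  Xd <- X
  if (nOrthogonal > 0) {
    for (j in seq_len(nOrthogonal)) {
      t <- drop(Xd %*% w)
      p <- drop(crossprod(Xd, t)) / sum(t^2)
      wo <- p - drop(crossprod(w, p)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break
      wo <- wo / nwo
      to <- drop(Xd %*% wo)
      po <- drop(crossprod(Xd, to)) / sum(to^2)
      Xd <- Xd - tcrossprod(to, po)
      orthoScores <- cbind(orthoScores, to)
      orthoLoadings <- cbind(orthoLoadings, po)
      r2xOrtho <- c(r2xOrtho, sum(to^2) * sum(po^2) / ssX)
    }
  }
  tp <- drop(Xd %*% w)
  pp <- drop(crossprod(Xd, tp)) / sum(tp^2)
  q <- sum(y * tp) / sum(tp^2)
  yhat <- tp * q
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  r2xPred <- sum(tp^2) * sum(pp^2) / ssX
  nOrthoUsed <- if (is.null(orthoScores)) 0L else ncol(orthoScores)
  scores <- cbind(tp, orthoScores)
  loadings <- cbind(pp, orthoLoadings)
  cn <- c("predictive",
          if (nOrthoUsed) paste0("orthogonal", seq_len(nOrthoUsed)))
  dimnames(scores) <- list(rownames(X), cn)
  dimnames(loadings) <- list(colnames(X), cn)
  nTop <- as.integer(ceiling(topFraction * ncol(X)))
  top <- colnames(X)[order(abs(pp), decreasing = TRUE)][seq_len(nTop)]
  new("OrdinationResult", scores = scores, loadings = loadings,
      explainedVariance = c(r2xPred, r2xOrtho), kind = "OPLSDA",
      componentType = c("predictive", rep("orthogonal", nOrthoUsed)),
      details = list(topLipids = top, topFraction = topFraction,
                     R2Y = r2y, weights = setNames(w, colnames(X)),
                     q = q, classes = cl))
}

#' Permutation test of the OPLS-DA class separation
#'
#' Refits the model under `nPermutations` random relabelings and compares
#' the observed predictive R2Y with the permutation distribution.
#'
#' @inheritParams oplsda
#' @param nPermutations Number of label permutations.
#' @param seed Optional integer seed.
#' @return A list: `observedR2Y`, `permutedR2Y`, and the permutation
#'   p-value `(1 + #{perm >= obs}) / (1 + nPermutations)`.
#' @export
oplsdaPermutationTest <- function(table, classes = "genotype",
                                  nOrthogonal = 1, nPermutations = 100,
                                  log2 = TRUE, scale = "uv",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length(classes) == 1L && is.character(classes))
    classes <- SummarizedExperiment::colData(table)[[classes]]
  cl <- factor(classes)
  obs <- oplsda(table, cl, nOrthogonal = nOrthogonal, log2 = log2,
                scale = scale)@details$R2Y
  perm <- vapply(seq_len(nPermutations), function(i) {
    oplsda(table, sample(cl), nOrthogonal = nOrthogonal, log2 = log2,
           scale = scale)@details$R2Y
  }, 0)
  list(observedR2Y = obs, permutedR2Y = perm,
       pValue = (1 + sum(perm >= obs)) / (1 + nPermutations))
}

#' Two-factor analysis of Euclidean distances between lipid profiles
#'
#' Tests whether genotype and diet structure the Euclidean distances
#' between preprocessed lipid profiles. The default is a two-factor
#' PERMANOVA ([vegan::adonis2()]), whose per-term R2 is reported as the
#' eta-squared analogue; `method = "centroid"` instead feeds each sample's
#' Euclidean distance to the grand centroid into [twoWayAnova()].
#'
#' @param table A [LipidTable-class].
#' @param factors Two `colData` column names.
#' @param method `"permanova"` (default) or `"centroid"`.
#' @param permutations Number of PERMANOVA permutations.
#' @param log2,scale Passed to [preprocessLipids()].
#' @param seed Optional seed for the permutations.
#' @return A named list of [TestResult-class], one per factor.
#' @export
distanceAnova <- function(table, factors = c("genotype", "diet"),
                          method = c("permanova", "centroid"),
                          permutations = 999, log2 = TRUE,
                          scale = c("uv", "pareto", "none"),
                          seed = NULL) {
  method <- match.arg(method)
  X <- preprocessLipids(table, log2 = log2, scale = match.arg(scale))
  cd <- as.data.frame(SummarizedExperiment::colData(table))
  if (!all(factors %in% colnames(cd)))
    stop("unknown sample factor(s): ",
         paste(setdiff(factors, colnames(cd)), collapse = ", "))
  fa <- factor(cd[[factors[1]]]); fb <- factor(cd[[factors[2]]])
  if (all(dist(X) == 0))
    stop("all samples are identical: distances are degenerate")
  if (method == "centroid") {
    ctr <- colMeans(X)
    di <- sqrt(rowSums(sweep(X, 2, ctr)^2))
    return(twoWayAnova(di, fa, fb, interaction = FALSE, names = factors))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  df <- data.frame(fa = fa, fb = fb)
  ad <- vegan::adonis2(dist(X) ~ fa + fb, data = df,
                       permutations = permutations, by = "terms")
  out <- lapply(c("fa", "fb"), function(term) {
    i <- match(term, rownames(ad))
    TestResult("two-factor PERMANOVA (Euclidean)",
               statistic = c(F = ad$F[i]),
               parameter = c(df = ad$Df[i]),
               pValue = ad$`Pr(>F)`[i],
               nPerGroup = nrow(X),
               effect = EffectSize("eta_squared", ad$R2[i]),
               details = list(permutations = permutations))
  })
  setNames(out, factors)
}
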