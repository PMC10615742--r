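#' Lipid abundance table with class and acyl-chain annotations
#'
#' `LipidTable` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `abundance` assay (lipids x samples, non-negative), per-lipid
#' annotations in `rowData` (`lipid_class`, and `acyl_chains` as a
#' semicolon-separated "C:D" string, e.g. `"16:0;22:6"`), and per-sample
#' factors (`genotype`, `diet`, `sex`, ...) in `colData`.
#'
#' @examples
#' m <- matrix(1:12, nrow = 3,
#'             dimnames = list(paste0("L", 1:3), paste0("S", 1:4)))
#' lt <- LipidTable(m, lipidClass = c("PC", "PC", "PE"),
#'                  acylChains = c("16:0;18:1", "16:0;20:4", "18:0;22:6"),
#'                  sampleData = data.frame(genotype = c("WT", "WT",
#'                                                       "MUT", "MUT")))
#' lipidClass(lt)
#' @export
setClass("LipidTable", contains = "SummarizedExperiment")

setValidity("LipidTable", function(object) {
  msg <- NULL
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'abundance' assay is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated lipid_id")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("lipid_class", "acyl_chains") %in% colnames(rd)))
    msg <- c(msg, "rowData needs 'lipid_class' and 'acyl_chains'")
  else if (any(is.na(rd$acyl_chains) | rd$acyl_chains == ""))
    msg <- c(msg, "every lipid needs at least one acyl chain")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @rdname LipidTable-class
#' @param abundance Lipids x samples numeric matrix with lipid ids as row
#'   names (sample ids as column names).
#' @param lipidClass Character vector of class abbreviations, one per lipid.
#' @param acylChains Acyl chains per lipid: a character vector of
#'   semicolon-separated `"C:D"` strings, or a list of character vectors.
#' @param sampleData Data frame of per-sample factors.
#' @export
LipidTable <- function(abundance, lipidClass, acylChains, sampleData) {
  abundance <- as.matrix(abundance)
  if (is.list(acylChains))
    acylChains <- vapply(acylChains, paste, "", collapse = ";")
  rd <- S4Vectors::DataFrame(lipid_class = as.character(lipidClass),
                             acyl_chains = as.character(acylChains),
                             row.names = rownames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), rowData = rd,
    colData = S4Vectors::DataFrame(sampleData,
                                   row.names = colnames(abundance)))
  new("LipidTable", se)
}

#' @describeIn LipidTable-class per-lipid class abbreviations
#' @param x A `LipidTable`.
#' @export
setMethod("lipidClass", "LipidTable", function(x)
  setNames(as.character(SummarizedExperiment::rowData(x)$lipid_class),
           rownames(x)))

#' @describeIn LipidTable-class acyl chains as a named list of character
#'   vectors, one element per lipid
#' @export
setMethod("acylChains", "LipidTable", function(x)
  setNames(strsplit(as.character(
    SummarizedExperiment::rowData(x)$acyl_chains), ";"), rownames(x)))

#' Read a lipid table from abundance, annotation and metadata files
#'
#' Expects the three-file layout used for quantified lipidomics tables:
#' an abundance matrix (first column `lipid_id`, one column per sample), a
#' lipid annotation table (`lipid_id`, `lipid_class`, `acyl_chains` with
#' semicolon-separated chains) and a sample metadata table (`sample_id`
#' plus factor columns). Files may be TSV or CSV (by extension). Lipid and
#' sample ids must match across files (order is reconciled); duplicated
#' lipid ids or dimension mismatches are errors, unknown class
#' abbreviations produce a warning but pass through, and zero or missing
#' abundances are counted in a message.
#'
#' @param abundancePath,annotationPath,metadataPath File paths.
#' @return A [LipidTable-class].
#' @export
readLipidTable <- function(abundancePath, annotationPath, metadataPath) {
  .rd <- function(p) {
    sep <- if (grepl("\\.tsv$|\\.txt$", p)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"")
  }
  ab <- .rd(abundancePath)
  an <- .rd(annotationPath)
  md <- .rd(metadataPath)
  if (anyDuplicated(ab[[1]]))
    stop("duplicated lipid_id in abundance table: ",
         ab[[1]][duplicated(ab[[1]])][1])
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab[[1]]
  if (!setequal(an$lipid_id, rownames(m)) ||
      nrow(an) != nrow(m))
    stop("lipid ids differ between abundance and annotation tables")
  an <- an[match(rownames(m), an$lipid_id), ]
  if (!setequal(md$sample_id, colnames(m)) || nrow(md) != ncol(m))
    stop("sample ids differ between abundance and metadata tables")
  md <- md[match(colnames(m), md$sample_id), , drop = FALSE]
  unknown <- setdiff(unique(an$lipid_class),
                     names(defaultLipidClassCounts(464)))
  if (length(unknown))
    warning("unknown lipid class abbreviation(s): ",
            paste(unknown, collapse = ", "))
  nz <- sum(is.na(m) | m == 0)
  if (nz > 0)
    message(nz, " zero or missing abundance value(s)")
  LipidTable(m, lipidClass = an$lipid_class, acylChains = an$acyl_chains,
             sampleData = md[, setdiff(names(md), "sample_id"),
                             drop = FALSE])
}

#' @rdname readLipidTable
#' @param table A [LipidTable-class] to write.
#' @param dir Output directory; files `abundance.tsv`, `annotation.tsv`,
#'   `samples.tsv` are created.
#' @export
writeLipidTable <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- SummarizedExperiment::assay(table, "abundance")
  ab <- data.frame(lipid_id = rownames(a), a, check.names = FALSE)
  an <- data.frame(lipid_id = rownames(a),
                   lipid_class = lipidClass(table),
                   acyl_chains = as.character(
                     SummarizedExperiment::rowData(table)$acyl_chains))
  md <- data.frame(sample_id = colnames(a),
                   as.data.frame(SummarizedExperiment::colData(table)))
  paths <- file.path(dir, c("abundance.tsv", "annotation.tsv",
                            "samples.tsv"))
  utils::write.table(ab, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(an, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(md, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Preprocess lipid abundances for multivariate analysis
#'
#' Returns a samples x lipids matrix: abundances are log2-transformed with
#' a per-lipid pseudocount of half the smallest positive value (so zeros
#' stay finite), mean-centered per lipid, and optionally scaled to unit
#' variance (autoscaling, the default) or by the square root of the
#' standard deviation (Pareto). Constant lipids are left centered at zero.
#'
#' @param table A [LipidTable-class].
#' @param log2 Log-transform abundances first.
#' @param scale `"uv"`, `"pareto"` or `"none"`.
#' @param center Mean-center each lipid.
#' @return A numeric matrix, samples in rows.
#' @export
preprocessLipids <- function(table, log2 = TRUE,
                             scale = c("uv", "pareto", "none"),
                             center = TRUE) {
  scale <- match.arg(scale)
  a <- SummarizedExperiment::assay(table, "abundance")
  if (log2) a <- logAbundance(a)
  X <- t(a)
  if (center) X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  if (scale != "none") {
    s <- apply(X, 2, sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    if (scale == "pareto") s <- sqrt(s)
    X <- sweep(X, 2, s, "/")
  }
  X
}

#' Log2 abundances with per-lipid pseudocount
#'
#' `log2(x + pseudocount)` where the pseudocount defaults to half the
#' smallest positive abundance of that lipid (1 if a lipid has none).
#'
#' @param a Lipids x samples abundance matrix.
#' @param pseudocount Optional fixed pseudocount for all lipids.
#' @return A matrix of the same shape.
#' @export
logAbundance <- function(a, pseudocount = NULL) {
  a <- as.matrix(a)
  if (is.null(pseudocount)) {
    pc <- apply(a, 1, function(r) {
      pos <- r[!is.na(r) & r > 0]
      if (length(pos)) min(pos) / 2 else 1
    })
  } else pc <- rep(pseudocount, nrow(a))
  log2(a + pc)
}
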