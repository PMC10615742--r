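## Shared 2x2 Fisher enrichment over an arbitrary category membership.
.enrichment <- function(selected, membership, categories) {
  background <- length(selected)
  rows <- lapply(categories, function(k) {
    inCat <- membership[[k]]
    a <- sum(selected & inCat)
    b <- sum(selected & !inCat)
    cc <- sum(!selected & inCat)
    dd <- sum(!selected & !inCat)
    ft <- fisherExact2x2(matrix(c(a, b, cc, dd), 2, byrow = TRUE))
    es <- effect(ft)
    data.frame(category = k, a = a, b = b, c = cc, d = dd,
               n_category = a + cc, n_selected = a + b,
               odds_ratio = ft@details$odds_ratio,
               phi = effectValue(es) * ifelse(effectSign(es) == 0, 1,
                                              effectSign(es)),
               p = pValue(ft), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjustPvalues(out$p, "bh")
  attr(out, "background") <- background
  out
}

#' Lipid-class enrichment of differentially changed lipids
#'
#' For every lipid class present in the tested background, a 2x2 Fisher's
#' exact test of selected/unselected vs in-class/out-of-class, with the phi
#' coefficient as effect size (signed: positive = over-representation).
#' The background is the set of testable lipids from the comparison;
#' classes with no background members are skipped. BH-adjusted p-values
#' are reported across categories; figure-style summaries conventionally
#' show the raw Fisher p.
#'
#' @param results Output of [differentialLipids()].
#' @param table The [LipidTable-class] the results came from.
#' @return A data frame, one row per class, with counts `a` (selected,
#'   in class), `b`, `c`, `d`, odds ratio, `phi`, `p` and `p_adj`.
#' @export
classEnrichment <- function(results, table) {
  keep <- results$tested
  res <- results[keep, ]
  cls <- lipidClass(table)[res$lipid_id]
  cats <- unique(cls)
  membership <- lapply(cats, function(k) cls == k)
  names(membership) <- cats
  .enrichment(res$selected, membership, cats)
}

#' Fatty-acid enrichment of differentially changed lipids
#'
#' As [classEnrichment()], but membership is lipid-level set membership
#' over the distinct acyl chains a lipid carries: a lipid with two 16:0
#' chains counts once for 16:0, and a lipid belongs to every distinct
#' chain it carries (multi-membership).
#'
#' @inheritParams classEnrichment
#' @return A data frame, one row per fatty acid.
#' @export
fattyAcidEnrichment <- function(results, table) {
  keep <- results$tested
  res <- results[keep, ]
  ch <- lapply(acylChains(table)[res$lipid_id], unique)
  cats <- sort(unique(unlist(ch)))
  membership <- lapply(cats, function(k)
    vapply(ch, function(v) k %in% v, TRUE))
  names(membership) <- cats
  .enrichment(res$selected, membership, cats)
}
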