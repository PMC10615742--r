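#' Result of a hypothesis test with its effect size
#'
#' A light-weight container pairing a test statistic and p-value with the
#' matching standardized effect size, as reported throughout the package:
#' Cohen's d for t-tests, r for rank tests, eta squared for ANOVA and phi
#' for Fisher's exact test.
#'
#' @slot method Human-readable test name.
#' @slot statistic Named numeric test statistic.
#' @slot parameter Named numeric parameters (degrees of freedom etc.).
#' @slot pValue Two-sided p-value in `[0, 1]`.
#' @slot nPerGroup Integer group sizes.
#' @slot effect An [EffectSize-class] or `NULL`.
#' @slot pAdjusted Multiplicity-adjusted p-value (`NA` until set).
#' @slot details List of method-specific extras (odds ratio, Z, flags...).
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 parameter = "numeric", pValue = "numeric",
                 nPerGroup = "integer", effect = "ANY",
                 pAdjusted = "numeric", details = "list"))

setValidity("TestResult", function(object) {
  msg <- NULL
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p < -1e-12 || p > 1 + 1e-12)
    msg <- c(msg, "pValue must be a single number in [0, 1]")
  if (!is.na(object@pAdjusted) &&
      object@pAdjusted < object@pValue - 1e-12)
    msg <- c(msg, "pAdjusted must be >= pValue")
  if (!is.null(object@effect) && !is(object@effect, "EffectSize"))
    msg <- c(msg, "effect must be an EffectSize or NULL")
  if (is.null(msg)) TRUE else msg
})

TestResult <- function(method, statistic, pValue, nPerGroup = integer(),
                       parameter = numeric(), effect = NULL,
                       pAdjusted = NA_real_, details = list()) {
  new("TestResult", method = method, statistic = statistic,
      parameter = parameter, pValue = min(max(pValue, 0), 1),
      nPerGroup = as.integer(nPerGroup), effect = effect,
      pAdjusted = pAdjusted, details = details)
}

#' @describeIn TestResult-class the p-value
#' @param x A `TestResult`.
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @describeIn TestResult-class the adjusted p-value (`NA` if unset)
#' @export
setMethod("pAdjusted", "TestResult", function(x) x@pAdjusted)

#' @describeIn TestResult-class set the adjusted p-value
#' @param value Replacement adjusted p-value.
#' @export
setMethod("pAdjusted<-", "TestResult", function(x, value) {
  x@pAdjusted <- as.numeric(value)
  validObject(x)
  x
})

#' @describeIn TestResult-class the attached [EffectSize-class] (or `NULL`)
#' @export
setMethod("effect", "TestResult", function(x) x@effect)

setMethod("show", "TestResult", function(object) {
  st <- paste(sprintf("%s = %.4g", names(object@statistic),
                      object@statistic), collapse = ", ")
  cat(sprintf("%s: %s, p = %.4g", object@method, st, object@pValue))
  if (!is.na(object@pAdjusted))
    cat(sprintf(" (adjusted %.4g)", object@pAdjusted))
  cat("\n")
  if (!is.null(object@effect)) show(object@effect)
})

#' Flatten test results to a serializable table
#'
#' Converts one `TestResult` or a (possibly named) list of them into a
#' data frame with the record layout
#' `{method, statistic, p, p_adj, effect_metric, effect_value, magnitude}`,
#' ready for TSV/JSON export.
#'
#' @param results A `TestResult` or list of `TestResult` objects.
#' @return A data frame, one row per result.
#' @export
testResultTable <- function(results) {
  if (is(results, "TestResult")) results <- list(results)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    es <- r@effect
    data.frame(
      name = if (!is.null(names(results))) names(results)[i] else
        as.character(i),
      method = r@method,
      statistic = unname(r@statistic[1]),
      p = r@pValue,
      p_adj = r@pAdjusted,
      effect_metric = if (is.null(es)) NA_character_ else es@metric,
      effect_value = if (is.null(es)) NA_real_ else es@value,
      magnitude = if (is.null(es)) NA_character_ else es@magnitude,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
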