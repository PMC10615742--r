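#' Standardized effect sizes with magnitude labels
#'
#' `EffectSize` stores one standardized effect size: the metric
#' (`cohens_d`, `rank_r`, `eta_squared` or `phi`), its absolute value, the
#' direction of the effect where one exists (sign of the mean difference for
#' Cohen's d, sign of Z for rank tests, sign of the association for phi) and
#' a conventional magnitude label.
#'
#' Magnitude labels follow the usual behavioural-science conventions, with
#' strict thresholds: for Cohen's d, values above 0.01, 0.2, 0.5 and 0.8 are
#' labelled very small, small, medium and large; for r and phi the small,
#' medium and large thresholds are 0.1, 0.3 and 0.5; for eta squared they are
#' 0.01, 0.06 and 0.14.
#'
#' @slot metric One of `"cohens_d"`, `"rank_r"`, `"eta_squared"`, `"phi"`.
#' @slot value Non-negative magnitude of the effect.
#' @slot sign Direction (-1, 0 or 1); 0 when the metric is unsigned.
#' @slot magnitude Label derived from `metric` and `value`.
#'
#' @examples
#' EffectSize("cohens_d", -1.2)   # large, sign -1
#' EffectSize("eta_squared", 0.061)
#' @export
setClass("EffectSize",
  representation(metric = "character", value = "numeric",
                 sign = "numeric", magnitude = "character"))

.ES_METRICS <- c("cohens_d", "rank_r", "eta_squared", "phi")

setValidity("EffectSize", function(object) {
  msg <- NULL
  if (!object@metric %in% .ES_METRICS)
    msg <- c(msg, sprintf("unknown effect-size metric '%s'", object@metric))
  if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
    msg <- c(msg, "value must be a single non-negative number")
  if (object@metric %in% c("rank_r", "phi", "eta_squared") &&
      object@value > 1 + 1e-8)
    msg <- c(msg, sprintf("%s must lie in [0, 1]", object@metric))
  if (!object@sign %in% c(-1, 0, 1))
    msg <- c(msg, "sign must be -1, 0 or 1")
  if (is.null(msg)) TRUE else msg
})

#' Magnitude label for an effect size
#'
#' Pure lookup from (metric, value) to the conventional label. Thresholds
#' are strict (`>`): d above 0.01/0.2/0.5/0.8 maps to very_small/small/
#' medium/large; r and phi above 0.1/0.3/0.5 and eta squared above
#' 0.01/0.06/0.14 map to small/medium/large. Values at or below the first
#' threshold are labelled `"none"`.
#'
#' @param metric One of `"cohens_d"`, `"rank_r"`, `"eta_squared"`, `"phi"`.
#' @param value Non-negative effect-size value.
#' @return A character label.
#' @examples
#' magnitudeLabel("cohens_d", 0.9)      # "large"
#' magnitudeLabel("eta_squared", 0.061) # "medium"
#' @export
magnitudeLabel <- function(metric, value) {
  if (length(metric) != 1L || !metric %in% .ES_METRICS)
    stop("unknown effect-size metric: ", paste(metric, collapse = ", "))
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    stop("'value' must be a single non-negative number")
  cuts <- switch(metric,
    cohens_d    = c(0.01, 0.2, 0.5, 0.8),
    rank_r      = c(0.1, 0.3, 0.5),
    phi         = c(0.1, 0.3, 0.5),
    eta_squared = c(0.01, 0.06, 0.14))
  labs <- if (metric == "cohens_d")
    c("none", "very_small", "small", "medium", "large")
  else c("none", "small", "medium", "large")
  labs[sum(value > cuts) + 1L]
}

#' Construct an EffectSize
#'
#' For the signed metrics (`cohens_d`, `phi`) a signed `value` may be given;
#' it is split into absolute value and direction. `rank_r` and
#' `eta_squared` are unsigned; a direction can still be recorded via `sign`.
#'
#' @param metric Effect-size metric.
#' @param value Effect-size value (possibly signed for d and phi).
#' @param sign Optional explicit direction (-1, 0, 1).
#' @return An [EffectSize-class] object.
#' @export
EffectSize <- function(metric, value, sign = NULL) {
  if (is.null(sign)) {
    sign <- if (metric %in% c("cohens_d", "phi")) sign(value) else 0
  }
  value <- abs(value)
  new("EffectSize", metric = metric, value = value, sign = as.numeric(sign),
      magnitude = magnitudeLabel(metric, value))
}

#' @describeIn EffectSize-class the metric name
#' @param x An `EffectSize`.
#' @export
setMethod("effectMetric", "EffectSize", function(x) x@metric)

#' @describeIn EffectSize-class the absolute effect value
#' @export
setMethod("effectValue", "EffectSize", function(x) x@value)

#' @describeIn EffectSize-class the direction (-1, 0, 1)
#' @export
setMethod("effectSign", "EffectSize", function(x) x@sign)

#' @describeIn EffectSize-class the magnitude label
#' @export
setMethod("magnitude", "EffectSize", function(x) x@magnitude)

setMethod("show", "EffectSize", function(object) {
  dir <- c(`-1` = " (negative direction)", `0` = "",
           `1` = " (positive direction)")[as.character(object@sign)]
  cat(sprintf("%s = %.4g [%s]%s\n", object@metric, object@value,
              object@magnitude, dir))
})

#' Cohen's d for two independent samples
#'
#' Standardized mean difference using the pooled standard deviation (n - 1
#' variances weighted by their degrees of freedom). The magnitude is
#' reported as an absolute value; the sign of `mean(x) - mean(y)` is kept in
#' the `sign` slot of the result.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return An [EffectSize-class] with metric `"cohens_d"`.
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5))  # d = 2, negative direction
#' @export
cohensD <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("cohensD needs at least two observations per group")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    stop("zero pooled variance: Cohen's d is undefined for these data")
  EffectSize("cohens_d", (mean(x) - mean(y)) / sqrt(sp2))
}

#' Benjamini-Hochberg or Bonferroni p-value adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two corrections
#' used throughout the package; output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (step-up false discovery rate) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")
#' @export
adjustPvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[method])
}
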