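#' @import methods
#' @importFrom stats anova aov as.dist cor dhyper dist df dnbinom filter
#'   hclust kruskal.test lm mad median na.omit p.adjust pf pnorm prcomp
#'   pt quantile rbinom rnbinom rnorm rpois runif sd setNames t.test var
#'   rexp
#' @importFrom utils read.csv write.csv head tail
#' @importFrom BiocGenerics counts
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))

#' @export
setGeneric("pAdjusted<-", function(x, value) standardGeneric("pAdjusted<-"))

#' @export
setGeneric("effect", function(x) standardGeneric("effect"))

#' @export
setGeneric("magnitude", function(x) standardGeneric("magnitude"))

#' @export
setGeneric("effectMetric", function(x) standardGeneric("effectMetric"))

#' @export
setGeneric("effectValue", function(x) standardGeneric("effectValue"))

#' @export
setGeneric("effectSign", function(x) standardGeneric("effectSign"))

#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @export
setGeneric("binMinutes", function(x) standardGeneric("binMinutes"))

#' @export
setGeneric("binsPerDay", function(x) standardGeneric("binsPerDay"))

#' @export
setGeneric("nDays", function(x) standardGeneric("nDays"))

#' @export
setGeneric("lightHours", function(x) standardGeneric("lightHours"))

#' @export
setGeneric("lipidClass", function(x) standardGeneric("lipidClass"))

#' @export
setGeneric("acylChains", function(x) standardGeneric("acylChains"))

#' @export
setGeneric("ordScores", function(x) standardGeneric("ordScores"))

#' @export
setGeneric("ordLoadings", function(x) standardGeneric("ordLoadings"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("componentType", function(x) standardGeneric("componentType"))
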