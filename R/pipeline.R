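#' Read a pipeline configuration file
#'
#' YAML key-value configuration driving both analysis arms; unspecified
#' keys fall back to the package defaults (see [defaultPipelineParams()]).
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaultPipelineParams(), cfg)
}

#' Default pipeline parameters
#'
#' All operational constants of both arms in one place: the HAB outlier
#' fence and window, the hypoactivity threshold and duration floor, the
#' delayed-activity morning window, and the lipid significance/effect-size
#' gate.
#'
#' @return A named list of parameter groups.
#' @export
defaultPipelineParams <- function() {
  list(
    hab = list(windowHours = 6, fenceMultiplier = 1.5, mergeGapHours = 1,
               minDurationHours = 6, refineHours = 1, maxMissingFrac = 0.2),
    de = list(delta = 0.3, minDurationDays = 14, smoothDays = 3),
    morningHours = 6,
    flankDays = 14,
    referenceDays = 183,
    groupFactor = "genotype",
    gate = list(p = 0.05, d = 0.8),
    variant = "welch",
    log2 = TRUE,
    scale = "uv",
    nOrthogonal = 1,
    topFraction = 0.01,
    seed = 1L)
}

## Delayed-activity contrast around one DE call: index during the episode
## vs the flanking windows before and after (NA when a flank is absent).
.delayedContrast <- function(series, call, morningHours, flankDays) {
  durDays <- call$end_day - call$start_day
  during <- delayedActivityIndex(series, call$start_day:(call$end_day - 1),
                                 morningHours = morningHours)
  beforeDays <- (call$start_day - flankDays):(call$start_day - 1)
  afterDays <- call$end_day:(call$end_day + flankDays - 1)
  before <- if (min(beforeDays) >= 1)
    delayedActivityIndex(series, beforeDays, morningHours = morningHours)
  else NA_real_
  after <- if (max(afterDays) <= nDays(series))
    delayedActivityIndex(series, afterDays, morningHours = morningHours)
  else NA_real_
  c(before = before, during = during, after = after)
}

#' Run the behavioural analysis arm
#'
#' For a cohort of activity recordings: detects HABs and depression-like
#' episodes per animal, normalizes counts to episode frequencies per 183
#' days, compares the frequencies between groups with U tests (effect size
#' r), and contrasts the delayed-activity index during each depression-like
#' episode against its flanking two-week windows with paired signed-rank
#' tests. The full resolved parameter set is embedded in the report.
#'
#' @param input A directory of activity CSVs (with YAML sidecars) or a
#'   list of [ActivitySeries-class] objects.
#' @param params Parameter overrides, merged over
#'   [defaultPipelineParams()].
#' @param outDir Optional output directory; writes `animals.tsv`,
#'   `episodes.tsv`, `delayed_activity.tsv` and `report.json`.
#' @return A report list: `parameters`, `animals`, `episodes`,
#'   `delayed`, `tests`.
#' @export
runBehaviorArm <- function(input, params = list(), outDir = NULL) {
  pp <- utils::modifyList(defaultPipelineParams(), params)
  if (is.character(input)) {
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files))
      stop("no activity CSV files found in ", input)
    input <- lapply(files, readActivityCSV)
  }
  animals <- list(); episodes <- list(); delayed <- list()
  for (s in input) {
    id <- subjectID(s)
    habs <- tryCatch(do.call(detectHABs, c(list(s), pp$hab)),
                     error = function(e)
                       stop("subject ", id, ": ", conditionMessage(e)))
    des <- tryCatch(do.call(detectHypoactivityEpisodes, c(list(s), pp$de)),
                    error = function(e)
                      stop("subject ", id, ": ", conditionMessage(e)))
    nd <- nDays(s)
    animals[[id]] <- data.frame(
      subject_id = id, sex = s@sex, genotype = s@genotype, diet = s@diet,
      observed_days = nd, n_hab = nrow(habs), n_de = nrow(des),
      hab_frequency = episodeFrequency(habs, nd, pp$referenceDays),
      de_frequency = episodeFrequency(des, nd, pp$referenceDays),
      delayed_activity = delayedActivityIndex(
        s, morningHours = pp$morningHours),
      stringsAsFactors = FALSE)
    ep <- rbind(
      if (nrow(habs)) data.frame(subject_id = id, kind = habs$kind,
                                 start = habs$start_bin,
                                 end = habs$end_bin, unit = "bin",
                                 duration = habs$duration_hours,
                                 score = habs$score),
      if (nrow(des)) data.frame(subject_id = id, kind = des$kind,
                                start = des$start_day, end = des$end_day,
                                unit = "day", duration = des$duration_days,
                                score = des$score))
    if (!is.null(ep)) episodes[[id]] <- ep
    if (nrow(des)) {
      for (k in seq_len(nrow(des))) {
        ct <- .delayedContrast(s, des[k, ], pp$morningHours, pp$flankDays)
        delayed[[paste(id, k)]] <- data.frame(
          subject_id = id, episode = k, before = ct["before"],
          during = ct["during"], after = ct["after"],
          stringsAsFactors = FALSE)
      }
    }
  }
  animals <- do.call(rbind, animals)
  episodes <- if (length(episodes)) do.call(rbind, episodes) else NULL
  delayed <- if (length(delayed)) do.call(rbind, delayed) else NULL
  rownames(animals) <- NULL

  tests <- list()
  grp <- animals[[pp$groupFactor]]
  .try <- function(expr) tryCatch(expr, error = function(e) NULL)
  if (!is.null(grp) && length(unique(grp)) == 2L &&
      min(table(grp)) >= 2L) {
    # degenerate contrasts (e.g. every animal at zero) are reported as NULL
    tests$hab_frequency <- .try(compareGroups(animals$hab_frequency, grp))
    tests$de_frequency <- .try(compareGroups(animals$de_frequency, grp))
  }
  if (!is.null(delayed)) {
    okB <- stats::complete.cases(delayed[, c("before", "during")])
    if (sum(okB) >= 2 && any(delayed$during[okB] != delayed$before[okB]))
      tests$delayed_during_vs_before <- compareGroups(
        delayed[okB, c("before", "during")], paired = TRUE)
    okA <- stats::complete.cases(delayed[, c("after", "during")])
    if (sum(okA) >= 2 && any(delayed$during[okA] != delayed$after[okA]))
      tests$delayed_during_vs_after <- compareGroups(
        delayed[okA, c("after", "during")], paired = TRUE)
  }
  report <- list(parameters = pp, animals = animals, episodes = episodes,
                 delayed = delayed, tests = tests)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(animals, file.path(outDir, "animals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(episodes))
      utils::write.table(episodes, file.path(outDir, "episodes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(delayed))
      utils::write.table(delayed,
                         file.path(outDir, "delayed_activity.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(parameters = pp,
           tests = if (length(tests)) testResultTable(tests) else NULL,
           n_animals = nrow(animals)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' Run the lipidomics analysis arm
#'
#' For a lipid table and a two-level comparison: differential analysis
#' with the joint significance/effect-size gate, lipid-class and
#' fatty-acid enrichment, PCA, hierarchical clustering (Newick dendrogram)
#' and OPLS-DA with top-fraction loading selection. The summary reports
#' the number of selected lipids and the significantly enriched
#' categories.
#'
#' @param input A [LipidTable-class], or a named list of paths
#'   (`abundance`, `annotation`, `metadata`) for [readLipidTable()].
#' @param comparison List with `factor` and optionally `levels` (two
#'   levels to compare, in (A, B) order).
#' @param params Parameter overrides over [defaultPipelineParams()].
#' @param outDir Optional output directory; writes `differential.tsv`,
#'   `class_enrichment.tsv`, `fatty_acid_enrichment.tsv`,
#'   `pca_scores.tsv`, `oplsda_loadings.tsv`, `dendrogram.nwk`,
#'   `report.json`.
#' @return A report list: `parameters`, `differential`, `classEnrichment`,
#'   `fattyAcidEnrichment`, `pca`, `dendrogram`, `oplsda`, `summary`.
#' @export
runLipidArm <- function(input, comparison = list(factor = "genotype"),
                        params = list(), outDir = NULL) {
  pp <- utils::modifyList(defaultPipelineParams(), params)
  if (!is(input, "LipidTable")) {
    input <- readLipidTable(input$abundance, input$annotation,
                            input$metadata)
  }
  fac <- comparison$factor %||% pp$groupFactor
  levs <- comparison$levels
  cd <- SummarizedExperiment::colData(input)
  if (is.null(levs)) levs <- unique(as.character(cd[[fac]]))[1:2]
  sub <- input[, as.character(cd[[fac]]) %in% levs]
  diff <- differentialLipids(sub, factor = fac, levelA = levs[1],
                             levelB = levs[2], variant = pp$variant,
                             log2 = pp$log2, gate = pp$gate)
  ce <- classEnrichment(diff, sub)
  fe <- fattyAcidEnrichment(diff, sub)
  pca <- pcaLipids(input, log2 = pp$log2, scale = pp$scale)
  hc <- hierarchicalClusteringLipids(input, log2 = pp$log2,
                                     scale = pp$scale)
  op <- oplsda(sub, factor(as.character(cd[[fac]][
    as.character(cd[[fac]]) %in% levs]), levels = levs),
    nOrthogonal = pp$nOrthogonal, topFraction = pp$topFraction,
    log2 = pp$log2, scale = pp$scale)
  summary <- list(
    n_lipids = nrow(input),
    n_classes = length(unique(lipidClass(input))),
    n_fatty_acids = length(unique(unlist(acylChains(input)))),
    comparison = paste(fac, paste(levs, collapse = " vs ")),
    n_tested = sum(diff$tested),
    n_selected = sum(diff$selected, na.rm = TRUE),
    significant_classes = ce$category[ce$p < 0.05],
    significant_fatty_acids = fe$category[fe$p < 0.05],
    top_oplsda_lipids = op@details$topLipids)
  report <- list(parameters = pp, differential = diff,
                 classEnrichment = ce, fattyAcidEnrichment = fe,
                 pca = pca, dendrogram = hc, oplsda = op,
                 summary = summary)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .wt <- function(d, f) utils::write.table(
      d, file.path(outDir, f), sep = "\t", row.names = FALSE,
      quote = FALSE)
    .wt(diff, "differential.tsv")
    .wt(ce, "class_enrichment.tsv")
    .wt(fe, "fatty_acid_enrichment.tsv")
    .wt(data.frame(sample_id = rownames(ordScores(pca)),
                   ordScores(pca), check.names = FALSE),
        "pca_scores.tsv")
    .wt(data.frame(lipid_id = rownames(ordLoadings(op)),
                   ordLoadings(op), check.names = FALSE),
        "oplsda_loadings.tsv")
    dendrogramNewick(hc, file.path(outDir, "dendrogram.nwk"))
    jsonlite::write_json(list(parameters = pp, summary = summary),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
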