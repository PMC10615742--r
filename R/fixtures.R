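#' Write a reproducible fixture bundle with ground truth
#'
#' Materializes simulated inputs for both analysis arms as plain-text
#' files: one activity CSV (+ YAML sidecar) per animal configuration and a
#' three-file lipid table, plus a JSON manifest recording every seed and
#' the injected ground truth, so the bundle can be regenerated
#' byte-identically.
#'
#' @param activityConfigs Named list of argument lists for
#'   [simulateActivity()] (each must include a `seed`).
#' @param lipidConfig Argument list for [simulateLipidomics()] (with a
#'   `seed`), or `NULL` to skip.
#' @param outDir Output directory (created if needed).
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
writeFixtureBundle <- function(activityConfigs = list(),
                               lipidConfig = NULL, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(activity = list(), lipidomics = NULL)
  for (nm in names(activityConfigs)) {
    cfg <- activityConfigs[[nm]]
    if (is.null(cfg$seed)) stop("activity config '", nm, "' lacks a seed")
    cfg$subjectID <- cfg$subjectID %||% nm
    sim <- do.call(simulateActivity, cfg)
    path <- file.path(outDir, paste0(nm, ".csv"))
    writeActivityCSV(sim$series, path)
    manifest$activity[[nm]] <- list(
      file = basename(path), seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "episodes")],
      episodes = lapply(cfg$episodes, unclass),
      n_episodes = nrow(sim$truth),
      truth = sim$truth)
  }
  if (!is.null(lipidConfig)) {
    if (is.null(lipidConfig$seed)) stop("lipid config lacks a seed")
    sim <- do.call(simulateLipidomics, lipidConfig)
    paths <- writeLipidTable(sim$table, file.path(outDir, "lipids"))
    manifest$lipidomics <- list(
      files = basename(paths), seed = lipidConfig$seed,
      n_lipids = nrow(sim$table), truth = sim$truth)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
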