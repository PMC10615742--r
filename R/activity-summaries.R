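#' Daily activity summaries
#'
#' Per-day totals split by light phase, with the per-day delayed-activity
#' fraction (activity in the first `morningHours` of the light phase over
#' the daily total; `NA` on days without activity). Days are ZT-aligned:
#' each day starts at lights-on.
#'
#' @param series An [ActivitySeries-class].
#' @param morningHours Width of the morning window within the light phase.
#' @return A data frame with columns `day_index`, `total_counts`,
#'   `light_phase_counts`, `dark_phase_counts`, `delayed_activity`.
#' @export
dailySummaries <- function(series, morningHours = 6) {
  bpd <- binsPerDay(series)
  nd <- nDays(series)
  if (nd < 1L) stop("the series contains no whole day")
  lb <- .lightBinsPerDay(series)
  mb <- as.integer(round(morningHours * 60 / binMinutes(series)))
  m <- matrix(counts(series), nrow = bpd)
  total <- colSums(m, na.rm = TRUE)
  light <- colSums(m[seq_len(lb), , drop = FALSE], na.rm = TRUE)
  morning <- colSums(m[seq_len(min(mb, lb)), , drop = FALSE], na.rm = TRUE)
  data.frame(day_index = seq_len(nd),
             total_counts = total,
             light_phase_counts = light,
             dark_phase_counts = total - light,
             delayed_activity = ifelse(total > 0, morning / total, NA_real_))
}

#' Double-plotted actogram matrix
#'
#' Builds the conventional double-plotted actogram raster: row i holds day
#' i concatenated with day i + 1, so activity drifting across the midnight
#' seam stays visually contiguous. The final row pads the missing day
#' n + 1 with `NA`.
#'
#' @param series An [ActivitySeries-class] with >= 2 whole days.
#' @return A numeric matrix with `nDays` rows and `2 * binsPerDay` columns.
#' @export
buildDoublePlottedActogram <- function(series) {
  nd <- nDays(series)
  if (nd < 2L) stop("a double-plotted actogram needs at least two days")
  bpd <- binsPerDay(series)
  m <- matrix(counts(series), nrow = bpd)
  nxt <- cbind(m[, -1, drop = FALSE], NA_real_)
  out <- t(rbind(m, nxt))
  dimnames(out) <- list(paste0("day", seq_len(nd)), NULL)
  out
}

#' Delayed activity index
#'
#' Quantifies circadian phase delay as the fraction of daily wheel running
#' that occurs in the early light phase (ZT0 to ZT`morningHours`), when a
#' nocturnal animal should be resting: the per-day morning fraction is
#' averaged over the requested days. The index lies in [0, 1]; days with
#' zero total activity are excluded, and the result is `NA` (with a
#' warning) if no day in the window has activity.
#'
#' @param series An [ActivitySeries-class].
#' @param days Integer vector of day indices (default: all days).
#' @param morningHours Width of the morning window, default 6 h (ZT0-ZT6).
#' @param mode `"morning"` (default) or `"light"` to use the whole light
#'   phase instead of the morning window (sensitivity analysis).
#' @return A single number in [0, 1], or `NA`.
#' @export
delayedActivityIndex <- function(series, days = NULL, morningHours = 6,
                                 mode = c("morning", "light")) {
  mode <- match.arg(mode)
  if (mode == "light") morningHours <- lightHours(series)
  ds <- dailySummaries(series, morningHours = morningHours)
  if (is.null(days)) days <- ds$day_index
  days <- days[days >= 1 & days <= nrow(ds)]
  idx <- ds$delayed_activity[days]
  if (all(is.na(idx))) {
    warning("no activity in the requested window: index undefined")
    return(NA_real_)
  }
  mean(idx, na.rm = TRUE)
}

#' Episode frequency per six months
#'
#' Normalizes an episode count to the conventional six-month (183-day)
#' reporting window: `count * 183 / observedDays`.
#'
#' @param calls An episode data frame (as returned by the detectors) or a
#'   single count.
#' @param observedDays Number of observed days (> 0).
#' @param referenceDays Reporting window, default 183.
#' @return Episodes per `referenceDays` days.
#' @examples
#' episodeFrequency(4, 305)  # 2.4
#' @export
episodeFrequency <- function(calls, observedDays, referenceDays = 183) {
  if (observedDays <= 0) stop("observedDays must be positive")
  n <- if (is.data.frame(calls)) nrow(calls) else as.numeric(calls)
  n * referenceDays / observedDays
}

#' Group comparison of per-animal statistics
#'
#' Convenience wrapper used by the behavioural arm: an unpaired two-group
#' comparison uses the Mann-Whitney U test with effect size r; a paired
#' (within-animal) contrast uses the Wilcoxon signed-rank test.
#'
#' @param values Numeric vector of per-animal statistics (frequencies,
#'   indices); for `paired = TRUE` a two-column matrix or data frame
#'   (before, after).
#' @param groups Two-level grouping factor (unpaired case).
#' @param paired Whether the contrast is within-animal.
#' @return A [TestResult-class].
#' @export
compareGroups <- function(values, groups = NULL, paired = FALSE) {
  if (paired) {
    values <- as.matrix(values)
    if (ncol(values) != 2L)
      stop("paired comparison needs a two-column (before, after) input")
    return(wilcoxonSignedRank(values[, 1], values[, 2]))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("unpaired comparison needs exactly two groups")
  sp <- split(as.numeric(values), groups)
  if (any(lengths(sp) < 2L))
    stop("need at least two animals per group")
  mannWhitneyU(sp[[1]], sp[[2]])
}
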