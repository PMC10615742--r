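#' Detect hyperactivity bouts (HABs)
#'
#' A HAB is a sustained stretch of wheel running far above the animal's own
#' norm: activity high enough to be a statistical outlier, lasting at least
#' `minDurationHours` (6 h by default, the duration floor being inclusive).
#'
#' Detection is in two stages. (1) Candidate screening: rolling
#' `windowHours`-hour window sums are computed over the whole series, and an
#' outlier fence is placed at Q3 + `fenceMultiplier` * IQR of their
#' distribution (the box-plot whisker convention); windows above the fence
#' are merged into candidate extents (gaps up to `mergeGapHours` are
#' bridged). (2) Boundary refinement: within each extent, a short
#' `refineHours`-hour rolling sum is compared against the fence rescaled to
#' that width, and maximal runs of elevated bins become the episode bounds.
#' Runs shorter than the duration floor are discarded. The score is the
#' exceedance of the strongest window, `(max window sum - fence) / IQR`.
#'
#' Because the fence is quantile-based, detection is invariant to rescaling
#' the counts by a positive constant. Missing bins contribute nothing to
#' window sums; windows with more than `maxMissingFrac` missing bins are
#' uncallable.
#'
#' @param series An [ActivitySeries-class] with >= 14 days of recording.
#' @param windowHours Screening window width in hours.
#' @param fenceMultiplier IQR multiplier for the outlier fence.
#' @param mergeGapHours Maximal gap bridged when merging elevated runs.
#' @param minDurationHours Episode duration floor (inclusive).
#' @param refineHours Width of the boundary-refinement window.
#' @param maxMissingFrac Maximal missing fraction for a callable window.
#' @return A data frame of calls: `kind`, `start_bin`, `end_bin`
#'   (half-open bin interval), `duration_hours`, `score`; zero rows when
#'   nothing exceeds the fence.
#' @export
detectHABs <- function(series, windowHours = 6, fenceMultiplier = 1.5,
                       mergeGapHours = 1, minDurationHours = 6,
                       refineHours = 1, maxMissingFrac = 0.2) {
  if (nDays(series) < 14L)
    stop("HAB detection needs at least 14 days to estimate the reference")
  bm <- binMinutes(series)
  x <- counts(series)
  if (all(is.na(x) | x == 0)) return(.emptyEpisodes("HAB"))
  wb <- max(1L, as.integer(round(windowHours * 60 / bm)))
  W <- .rollSumLeft(x, wb, maxNAFrac = maxMissingFrac)
  q <- quantile(W, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr <= 0)
    stop("zero IQR of reference window sums: outlier fence is undefined")
  fence <- q[2] + fenceMultiplier * iqr
  hot <- !is.na(W) & W > fence
  if (!any(hot)) return(.emptyEpisodes("HAB"))
  gapBins <- as.integer(round(mergeGapHours * 60 / bm))
  runs <- .trueRuns(hot)
  ext <- data.frame(start = runs$start,
                    end = pmin(runs$end + wb - 1L, length(x)))
  ext <- .mergeIntervals(ext, maxGap = gapBins)
  rb <- max(1L, as.integer(round(refineHours * 60 / bm)))
  R <- .rollSumCentered(x, rb)
  thr <- fence * rb / wb
  calls <- .emptyEpisodes("HAB")
  for (i in seq_len(nrow(ext))) {
    span <- ext$start[i]:ext$end[i]
    sub <- .trueRuns(R[span] > thr)
    if (nrow(sub) == 0L) next
    sub <- .mergeIntervals(sub, maxGap = gapBins)
    for (j in seq_len(nrow(sub))) {
      s <- span[1] + sub$start[j] - 1L
      e <- span[1] + sub$end[j] - 1L
      durH <- (e - s + 1L) * bm / 60
      if (durH < minDurationHours) next
      ws <- max(1L, s - wb + 1L):min(e, length(W))
      score <- (max(W[ws], na.rm = TRUE) - fence) / iqr
      calls <- rbind(calls, data.frame(
        kind = "HAB", start_bin = s, end_bin = e + 1L,
        duration_hours = durH, score = score, stringsAsFactors = FALSE))
    }
  }
  calls[order(calls$start_bin), , drop = FALSE]
}

#' Detect depression-like hypoactivity episodes
#'
#' A depression-like episode is a stretch of at least `minDurationDays`
#' consecutive days (14 by default, inclusive) whose smoothed daily totals
#' fall below `(1 - delta)` times the animal's baseline. Daily totals are
#' smoothed with a `smoothDays`-day centered moving average; the baseline
#' is the median daily total, re-estimated once after initial flagging with
#' the flagged days excluded. The score is the mean fractional deficit
#' relative to the baseline over the episode days.
#'
#' @param series An [ActivitySeries-class] with >= 8 weeks of recording.
#' @param delta Fractional reduction threshold: days below
#'   `(1 - delta) * baseline` are candidate episode days.
#' @param minDurationDays Episode duration floor in days (inclusive).
#' @param smoothDays Width of the centered moving average.
#' @return A data frame of calls: `kind`, `start_day`, `end_day`
#'   (half-open day interval), `duration_days`, `score`.
#' @export
detectHypoactivityEpisodes <- function(series, delta = 0.3,
                                       minDurationDays = 14,
                                       smoothDays = 3) {
  if (nDays(series) < 56L)
    stop("hypoactivity detection needs at least 8 weeks of recording")
  ds <- dailySummaries(series)
  tot <- ds$total_counts
  S <- .rollSumCentered(tot, smoothDays) / smoothDays
  base <- median(tot)
  if (base <= 0)
    stop("zero baseline median daily activity")
  flag0 <- S < (1 - delta) * base
  if (any(!flag0)) {
    base <- median(tot[!flag0])
    if (base <= 0) stop("zero baseline median daily activity")
  }
  flag <- S < (1 - delta) * base
  runs <- .trueRuns(flag)
  runs <- runs[runs$end - runs$start + 1L >= minDurationDays, , drop = FALSE]
  if (nrow(runs) == 0L) return(.emptyEpisodes("DE"))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    d <- runs$start[i]:runs$end[i]
    data.frame(kind = "DEPRESSION_LIKE", start_day = runs$start[i],
               end_day = runs$end[i] + 1L,
               duration_days = length(d),
               score = mean(1 - S[d] / base),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
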