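#' Episode specifications for the activity simulator
#'
#' `habSpec()` describes a mania-like hyperactivity bout: for
#' `durationHours` (6-24 h) starting at `onsetHour` (ZT) of `onsetDay`, the
#' animal runs around the clock at `amplitude` times the nocturnal
#' (dark-phase) rate, regardless of light phase - the defining feature of
#' these bouts being sustained running even in the rest phase.
#'
#' `deSpec()` describes a depression-like hypoactivity episode: for
#' `durationDays` (>= 14) starting on `onsetDay`, expected activity is
#' multiplied by `amplitude` (< 1) and a fraction `lightRedistribution` of
#' the remaining activity is moved into the early light phase (ZT0-ZT6),
#' producing the phase-delayed running the delayed-activity index measures.
#'
#' @param onsetDay 1-based day of onset.
#' @param onsetHour ZT hour of HAB onset within that day.
#' @param durationHours HAB duration, in [6, 24].
#' @param durationDays Episode duration in days, >= 14.
#' @param amplitude Multiplicative factor on expected rates (> 1 for HAB,
#'   in (0, 1) for the hypoactive episode).
#' @param lightRedistribution Fraction of episode activity moved into the
#'   morning window.
#' @return A list with class `"EpisodeSpec"`.
#' @export
habSpec <- function(onsetDay, onsetHour = 12, durationHours = 12,
                    amplitude = 5) {
  if (durationHours < 6 || durationHours > 24)
    stop("HAB duration must lie in [6, 24] hours")
  if (amplitude <= 1) stop("HAB amplitude must exceed 1")
  structure(list(kind = "HAB", onsetDay = onsetDay, onsetHour = onsetHour,
                 durationHours = durationHours, amplitude = amplitude),
            class = "EpisodeSpec")
}

#' @rdname habSpec
#' @export
deSpec <- function(onsetDay, durationDays = 21, amplitude = 0.5,
                   lightRedistribution = 0.35) {
  if (durationDays < 14)
    stop("depression-like episodes last at least 14 days")
  if (amplitude <= 0 || amplitude >= 1)
    stop("hypoactivity amplitude must lie in (0, 1)")
  structure(list(kind = "DEPRESSION_LIKE", onsetDay = onsetDay,
                 durationDays = durationDays, amplitude = amplitude,
                 lightRedistribution = lightRedistribution),
            class = "EpisodeSpec")
}

#' Simulate a wheel-running activity series with known episodes
#'
#' Generates a nocturnal circadian count series under a 12:12 light-dark
#' schedule (by default): negative-binomial counts per bin around a
#' phase-dependent mean (square wave by default, cosine ramp optionally),
#' with injected hyperactivity bouts and/or depression-like episodes as
#' specified. The defaults emulate a C57BL/6-scale wheel-running record in
#' 6-minute bins: 20 expected revolutions per dark bin, 3 per light bin,
#' negative-binomial size 8 per bin. Identical seeds give identical series.
#'
#' @param nDays Number of simulated days.
#' @param binMinutes Bin width (divisor of 1440).
#' @param darkMean,lightMean Expected counts per dark/light bin
#'   (`darkMean > lightMean >= 0`, nocturnal).
#' @param dispersion Negative-binomial size parameter per bin.
#' @param episodes List of [habSpec()] / [deSpec()] objects; overlapping
#'   specs of the same kind are an error.
#' @param family `"nbinom"` (default) or `"poisson"`.
#' @param waveform `"square"` (default) or `"cosine"` circadian shape.
#' @param morningHours Morning window receiving redistributed activity.
#' @param lightsOnHour,lightsOffHour Clock hours of the light schedule.
#' @param subjectID,sex,genotype,diet Metadata for the resulting series.
#' @param seed Optional integer seed.
#' @return A list with elements `series` (an [ActivitySeries-class]) and
#'   `truth` (a data frame of injected episodes with their bin/day bounds).
#' @export
simulateActivity <- function(nDays = 183, binMinutes = 6, darkMean = 20,
                             lightMean = 3, dispersion = 8,
                             episodes = list(),
                             family = c("nbinom", "poisson"),
                             waveform = c("square", "cosine"),
                             morningHours = 6,
                             lightsOnHour = 8, lightsOffHour = 20,
                             subjectID = "sim", sex = "F",
                             genotype = "sim", diet = "chow",
                             seed = NULL) {
  family <- match.arg(family)
  waveform <- match.arg(waveform)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (darkMean <= lightMean || lightMean < 0)
    stop("need darkMean > lightMean >= 0 (nocturnal pattern)")
  bpd <- 1440L %/% as.integer(binMinutes)
  lightH <- (lightsOffHour - lightsOnHour) %% 24
  lb <- as.integer(round(lightH * 60 / binMinutes))
  binHour <- (seq_len(bpd) - 0.5) * binMinutes / 60  # ZT at bin center
  dayRate <- if (waveform == "square") {
    ifelse(seq_len(bpd) <= lb, lightMean, darkMean)
  } else {
    mid <- (darkMean + lightMean) / 2
    amp <- (darkMean - lightMean) / 2
    peak <- lightH + (24 - lightH) / 2  # middle of the dark phase
    mid + amp * cos(2 * pi * (binHour - peak) / 24)
  }
  rate <- rep(dayRate, nDays)
  n <- length(rate)
  mb <- as.integer(round(morningHours * 60 / binMinutes))

  .asBin <- function(day, hour) as.integer((day - 1L) * bpd +
                                             floor(hour * 60 / binMinutes)) + 1L
  truth <- list()
  ivByKind <- list()
  for (ep in episodes) {
    if (!inherits(ep, "EpisodeSpec")) stop("episodes must be EpisodeSpec")
    if (ep$kind == "HAB") {
      s <- .asBin(ep$onsetDay, ep$onsetHour)
      e <- s + as.integer(round(ep$durationHours * 60 / binMinutes)) - 1L
      if (s < 1L || e > n) stop("HAB spec falls outside the recording")
      iv <- c(s, e)
      rate[s:e] <- ep$amplitude * darkMean
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "HAB", start_bin = s, end_bin = e + 1L,
        start_day = (s - 1L) %/% bpd + 1L,
        end_day = (e - 1L) %/% bpd + 2L,  # half-open, like end_bin
        amplitude = ep$amplitude, stringsAsFactors = FALSE)
    } else {
      d0 <- ep$onsetDay
      d1 <- d0 + ep$durationDays - 1L
      if (d0 < 1L || d1 > nDays) stop("episode spec falls outside the recording")
      iv <- c(d0, d1)
      f <- ep$lightRedistribution
      for (d in d0:d1) {
        bins <- ((d - 1L) * bpd + 1L):(d * bpd)
        E <- ep$amplitude * sum(dayRate)
        newRate <- (1 - f) * ep$amplitude * dayRate
        newRate[seq_len(mb)] <- newRate[seq_len(mb)] + f * E / mb
        rate[bins] <- newRate
      }
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "DEPRESSION_LIKE", start_bin = (d0 - 1L) * bpd + 1L,
        end_bin = d1 * bpd + 1L, start_day = d0, end_day = d1 + 1L,
        amplitude = ep$amplitude, stringsAsFactors = FALSE)
    }
    prev <- ivByKind[[ep$kind]]
    if (!is.null(prev)) {
      for (p in prev)
        if (iv[1] <= p[2] && p[1] <= iv[2])
          stop("overlapping episode specs of kind ", ep$kind)
    }
    ivByKind[[ep$kind]] <- c(ivByKind[[ep$kind]], list(iv))
  }
  x <- switch(family,
    nbinom = rnbinom(n, mu = rate, size = dispersion),
    poisson = rpois(n, lambda = rate))
  series <- ActivitySeries(x, binMinutes = binMinutes,
                           subjectID = subjectID, sex = sex,
                           genotype = genotype, diet = diet,
                           lightsOnHour = lightsOnHour,
                           lightsOffHour = lightsOffHour)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), start_bin = integer(),
               end_bin = integer(), start_day = integer(),
               end_day = integer(), amplitude = numeric(),
               stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}
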