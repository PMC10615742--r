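#' One animal's binned wheel-running record
#'
#' `ActivitySeries` holds wheel-revolution counts in fixed-width bins for a
#' single animal over whole recording days, together with the light
#' schedule and animal metadata. The series is aligned to Zeitgeber time:
#' the first bin starts at lights-on (ZT0) of day 1, so each day consists
#' of the light phase (ZT0 to ZT`lightHours`) followed by the dark phase.
#' Missing bins are explicit `NA`s, never zeros.
#'
#' @slot subjectID Animal identifier.
#' @slot sex,genotype,diet Animal metadata (free-form strings).
#' @slot binMinutes Bin width in minutes; must divide 1440.
#' @slot counts Numeric vector of non-negative counts (NA = missing),
#'   spanning whole days.
#' @slot lightsOnHour,lightsOffHour Clock hours of lights-on/off; their
#'   difference (mod 24) is the light-phase duration, 12 h by default.
#'
#' @examples
#' s <- ActivitySeries(counts = rep(c(0, 5), each = 120), binMinutes = 6)
#' nDays(s)
#' @export
setClass("ActivitySeries",
  representation(subjectID = "character", sex = "character",
                 genotype = "character", diet = "character",
                 binMinutes = "integer", counts = "numeric",
                 lightsOnHour = "numeric", lightsOffHour = "numeric"))

setValidity("ActivitySeries", function(object) {
  msg <- NULL
  bm <- object@binMinutes
  if (length(bm) != 1L || is.na(bm) || bm < 1L || 1440L %% bm != 0L)
    msg <- c(msg, "binMinutes must be a positive divisor of 1440")
  else {
    bpd <- 1440L %/% bm
    if (length(object@counts) %% bpd != 0L)
      msg <- c(msg, "counts must span whole days")
  }
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  lh <- (object@lightsOffHour - object@lightsOnHour) %% 24
  if (lh <= 0 || lh >= 24)
    msg <- c(msg, "light phase duration must be in (0, 24) hours")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ActivitySeries-class
#' @param counts,binMinutes,subjectID,sex,genotype,diet,lightsOnHour,lightsOffHour
#'   See slots.
#' @export
ActivitySeries <- function(counts, binMinutes = 6, subjectID = "animal",
                           sex = NA_character_, genotype = NA_character_,
                           diet = NA_character_, lightsOnHour = 8,
                           lightsOffHour = 20) {
  new("ActivitySeries", subjectID = as.character(subjectID),
      sex = as.character(sex), genotype = as.character(genotype),
      diet = as.character(diet), binMinutes = as.integer(binMinutes),
      counts = as.numeric(counts), lightsOnHour = as.numeric(lightsOnHour),
      lightsOffHour = as.numeric(lightsOffHour))
}

#' @describeIn ActivitySeries-class the animal identifier
#' @param x An `ActivitySeries`.
#' @export
setMethod("subjectID", "ActivitySeries", function(x) x@subjectID)

#' @describeIn ActivitySeries-class the bin width in minutes
#' @export
setMethod("binMinutes", "ActivitySeries", function(x) x@binMinutes)

#' @describeIn ActivitySeries-class bins per day
#' @export
setMethod("binsPerDay", "ActivitySeries",
          function(x) 1440L %/% x@binMinutes)

#' @describeIn ActivitySeries-class number of whole recording days
#' @export
setMethod("nDays", "ActivitySeries",
          function(x) length(x@counts) %/% binsPerDay(x))

#' @describeIn ActivitySeries-class light-phase duration in hours
#' @export
setMethod("lightHours", "ActivitySeries",
          function(x) (x@lightsOffHour - x@lightsOnHour) %% 24)

#' @describeIn ActivitySeries-class the count vector
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "ActivitySeries", function(object, ...) object@counts)

setMethod("show", "ActivitySeries", function(object) {
  cat(sprintf(
    "ActivitySeries '%s': %d days of %d-min bins (%d bins), %g h light\n",
    object@subjectID, nDays(object), object@binMinutes,
    length(object@counts), lightHours(object)))
  cat(sprintf("  sex=%s genotype=%s diet=%s; %d missing bins\n",
              object@sex, object@genotype, object@diet,
              sum(is.na(object@counts))))
})

## bins of day d (1-based), and the light-phase bin mask within one day
.dayBins <- function(series, d) {
  bpd <- binsPerDay(series)
  ((d - 1L) * bpd + 1L):(d * bpd)
}

.lightBinsPerDay <- function(series) {
  as.integer(round(lightHours(series) * 60 / binMinutes(series)))
}

#' Read / write an activity CSV with its metadata sidecar
#'
#' The CSV has columns `subject_id`, `bin` (1-based bin index) and `counts`;
#' animal metadata and the light schedule live in a YAML sidecar (same path
#' with extension `.yaml`) with keys `sex`, `genotype`, `diet`,
#' `bin_minutes`, `lights_on`, `lights_off`. Gaps in the bin index become
#' explicit `NA` bins; trailing bins that do not complete a day are trimmed
#' with a warning. Negative counts or a non-monotone bin index raise an
#' error naming the offending row.
#'
#' @param path CSV file path.
#' @param sidecar Optional explicit sidecar path.
#' @return An [ActivitySeries-class].
#' @export
readActivityCSV <- function(path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- sub("\\.csv$", ".yaml", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "bin", "counts")
  if (!all(need %in% names(df)))
    stop("activity CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.na(df$counts) & df$counts < 0)
  if (length(bad))
    stop(sprintf("negative count at row %d of %s", bad[1], path))
  if (any(diff(df$bin) <= 0))
    stop(sprintf("non-monotone bin index at row %d of %s",
                 which(diff(df$bin) <= 0)[1] + 1L, path))
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  bm <- as.integer(meta$bin_minutes %||% 6L)
  n <- as.integer(meta$n_bins %||% max(df$bin))
  x <- rep(NA_real_, n)
  x[df$bin] <- df$counts
  bpd <- 1440L %/% bm
  if (n %% bpd != 0L) {
    warning("trimming ", n %% bpd, " trailing bins of a partial day")
    x <- x[seq_len((n %/% bpd) * bpd)]
  }
  ActivitySeries(x, binMinutes = bm, subjectID = df$subject_id[1],
                 sex = meta$sex %||% NA_character_,
                 genotype = meta$genotype %||% NA_character_,
                 diet = meta$diet %||% NA_character_,
                 lightsOnHour = meta$lights_on %||% 8,
                 lightsOffHour = meta$lights_off %||% 20)
}

#' @rdname readActivityCSV
#' @param series An [ActivitySeries-class] to write.
#' @export
writeActivityCSV <- function(series, path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- sub("\\.csv$", ".yaml", path)
  x <- counts(series)
  df <- data.frame(subject_id = subjectID(series),
                   bin = seq_along(x), counts = x)
  df <- df[!is.na(df$counts), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sex = series@sex, genotype = series@genotype,
                        diet = series@diet,
                        bin_minutes = as.integer(binMinutes(series)),
                        lights_on = series@lightsOnHour,
                        lights_off = series@lightsOffHour,
                        n_bins = length(x)),
                   sidecar)
  invisible(c(path, sidecar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
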