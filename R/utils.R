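## Internal helpers shared by the actigraphy and simulation code.

## Left-aligned rolling sum of k bins. Missing bins contribute 0 to the sum
## but are counted; windows whose missing fraction exceeds maxNAFrac are
## reported as NA (uncallable).
.rollSumLeft <- function(x, k, maxNAFrac = 1) {
  n <- length(x)
  if (k > n) return(numeric(0))
  xz <- x
  xz[is.na(xz)] <- 0
  cs <- c(0, cumsum(xz))
  s <- cs[(k + 1):(n + 1)] - cs[seq_len(n - k + 1)]
  cn <- c(0, cumsum(is.na(x)))
  nna <- cn[(k + 1):(n + 1)] - cn[seq_len(n - k + 1)]
  s[nna / k > maxNAFrac] <- NA_real_
  s
}

## Centered rolling sum, same length as x (edges use truncated windows,
## rescaled to the full window width so edge values stay comparable).
.rollSumCentered <- function(x, k) {
  n <- length(x)
  xz <- x
  xz[is.na(xz)] <- 0
  half <- k %/% 2
  cs <- c(0, cumsum(xz))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) - half + k - 1L, n)
  s <- cs[hi + 1L] - cs[lo]
  s * k / (hi - lo + 1L)
}

## Runs of TRUE in a logical vector -> data.frame(start, end) (inclusive).
.trueRuns <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Merge intervals (inclusive, sorted by start) whose gap is <= maxGap.
.mergeIntervals <- function(iv, maxGap = 0L) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$start[i] - out$end[j] - 1L <= maxGap) {
      out$end[j] <- max(out$end[j], iv$end[i])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

## Seeded sub-stream helper: derives a reproducible 31-bit integer seed.
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629
}

.emptyEpisodes <- function(kind) {
  if (kind == "HAB") {
    data.frame(kind = character(), start_bin = integer(),
               end_bin = integer(), duration_hours = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), start_day = integer(),
               end_day = integer(), duration_days = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  }
}
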