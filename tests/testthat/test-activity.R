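test_that("ActivitySeries validates its structure", {
  expect_s4_class(ActivitySeries(rep(0, 240), binMinutes = 6),
                  "ActivitySeries")
  expect_error(ActivitySeries(rep(0, 250), binMinutes = 6), "whole days")
  expect_error(ActivitySeries(rep(0, 240), binMinutes = 7), "divisor")
  expect_error(ActivitySeries(c(rep(0, 239), -1), binMinutes = 6),
               "non-negative")
  s <- ActivitySeries(rep(1, 480), binMinutes = 6)
  expect_equal(nDays(s), 2)
  expect_equal(binsPerDay(s), 240)
  expect_equal(lightHours(s), 12)
})

test_that("activity CSV round trip preserves counts, gaps and metadata", {
  x <- rpois(480, 5)
  x[c(13, 400:480)] <- NA  # an interior gap and a missing tail
  s <- ActivitySeries(x, binMinutes = 6, subjectID = "m1", sex = "M",
                      genotype = "mut", diet = "chow")
  csv <- file.path(withr::local_tempdir(), "m1.csv")
  writeActivityCSV(s, csv)
  s2 <- readActivityCSV(csv)
  expect_equal(counts(s2), counts(s))
  expect_equal(subjectID(s2), "m1")
  expect_equal(s2@genotype, "mut")
  expect_equal(binMinutes(s2), 6)
})

test_that("malformed activity CSVs fail with the offending row named", {
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "bad.csv")
  writeLines(c("subject_id,bin,counts", "a,1,3", "a,2,-4", "a,3,1"), csv)
  expect_error(readActivityCSV(csv), "negative count at row 2")
  writeLines(c("subject_id,bin,counts", "a,2,3", "a,1,4"), csv)
  expect_error(readActivityCSV(csv), "non-monotone")
})

test_that("daily summaries split counts by light phase correctly", {
  s <- ActivitySeries(rep(1, 480), binMinutes = 6)  # constant 1 per bin
  ds <- dailySummaries(s)
  expect_equal(nrow(ds), 2)
  expect_equal(ds$total_counts, c(240, 240))
  expect_equal(ds$light_phase_counts, c(120, 120))
  expect_equal(ds$dark_phase_counts, c(120, 120))
  expect_equal(ds$total_counts,
               ds$light_phase_counts + ds$dark_phase_counts)

  # all activity in the dark phase
  day <- c(rep(0, 120), rep(4, 120))
  sd <- ActivitySeries(rep(day, 3), binMinutes = 6)
  dsd <- dailySummaries(sd)
  expect_true(all(dsd$light_phase_counts == 0))
  expect_equal(dsd$delayed_activity, rep(0, 3))
})

test_that("simulated nocturnal animals are strongly dark-active", {
  sim <- simulateActivity(nDays = 60, seed = 101)
  ds <- dailySummaries(sim$series)
  frac <- ds$dark_phase_counts / ds$total_counts
  expect_gte(mean(frac > 0.8), 0.95)
})

test_that("the double-plotted actogram duplicates consecutive days", {
  s <- ActivitySeries(rpois(720, 3), binMinutes = 6)  # 3 days
  m <- buildDoublePlottedActogram(s)
  expect_equal(dim(m), c(3, 480))
  expect_equal(m[1, 241:480], m[2, 1:240])
  expect_equal(m[2, 241:480], m[3, 1:240])
  expect_true(all(is.na(m[3, 241:480])))
  expect_error(
    buildDoublePlottedActogram(ActivitySeries(rep(0, 240), binMinutes = 6)),
    "two days")
})

test_that("a bout spanning midnight is contiguous across the seam", {
  # elevated run from late day 2 into early day 3
  sim <- simulateActivity(nDays = 5, episodes = list(
    habSpec(onsetDay = 2, onsetHour = 20, durationHours = 10,
            amplitude = 5)), seed = 55)
  m <- buildDoublePlottedActogram(sim$series)
  expect_equal(m[2, 241:480], m[3, 1:240])
})

test_that("delayed activity index is the morning-light fraction in [0,1]", {
  day <- c(rep(6, 60), rep(0, 180))  # everything in ZT0-ZT6
  s <- ActivitySeries(rep(day, 2), binMinutes = 6)
  expect_equal(delayedActivityIndex(s), 1)

  dark <- c(rep(0, 120), rep(6, 120))
  s2 <- ActivitySeries(rep(dark, 2), binMinutes = 6)
  expect_equal(delayedActivityIndex(s2), 0)

  s3 <- ActivitySeries(rep(0, 480), binMinutes = 6)
  expect_warning(v <- delayedActivityIndex(s3), "undefined")
  expect_true(is.na(v))

  sim <- simulateActivity(nDays = 30, seed = 9)
  v <- delayedActivityIndex(sim$series)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("episode frequency normalizes to the 183-day window", {
  expect_equal(episodeFrequency(0, 100), 0)
  expect_equal(episodeFrequency(2, 366), 1)
  expect_equal(episodeFrequency(4, 305), 2.4)
  expect_error(episodeFrequency(1, 0), "positive")
})

test_that("compareGroups dispatches to the right rank test", {
  set.seed(77)
  vals <- c(rnorm(8, 2), rnorm(8, 0))
  grp <- rep(c("mut", "wt"), each = 8)
  r <- compareGroups(vals, grp)
  expect_equal(r@method, "Mann-Whitney U test")
  rp <- compareGroups(cbind(before = rnorm(8), after = rnorm(8) + 3),
                      paired = TRUE)
  expect_equal(rp@method, "Wilcoxon signed-rank test")
  expect_error(compareGroups(vals, rep("g", 16)), "two groups")
})
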