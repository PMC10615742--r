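test_that("an injected 12-h bout yields exactly one accurate HAB call", {
  sim <- simulateActivity(nDays = 60, episodes = list(
    habSpec(onsetDay = 20, onsetHour = 14, durationHours = 12,
            amplitude = 5)), seed = 42)
  calls <- detectHABs(sim$series)
  expect_equal(nrow(calls), 1)
  expect_gte(jaccardInterval(calls$start_bin, calls$end_bin,
                             sim$truth$start_bin, sim$truth$end_bin), 0.8)
  expect_gte(calls$duration_hours, 6)
  expect_gt(calls$score, 0)
})

test_that("sub-threshold bursts and quiet series produce no HAB calls", {
  # a 3-h burst at 5x fails the 6-h duration floor
  base <- simulateActivity(nDays = 60, seed = 8)
  x <- counts(base$series)
  bpd <- binsPerDay(base$series)
  burst <- (19 * bpd + 130):(19 * bpd + 159)  # 3 h in the dark phase
  set.seed(1); x[burst] <- rnbinom(length(burst), mu = 100, size = 8)
  expect_equal(nrow(detectHABs(ActivitySeries(x, binMinutes = 6))), 0)

  # constant-rate noise only
  expect_equal(nrow(detectHABs(simulateActivity(nDays = 60,
                                                seed = 3)$series)), 0)
  # all-zero series is an empty result, not an error
  z <- ActivitySeries(rep(0, 240 * 20), binMinutes = 6)
  expect_equal(nrow(detectHABs(z)), 0)
})

test_that("HAB detection preconditions and degenerate inputs error", {
  short <- ActivitySeries(rpois(240 * 10, 3), binMinutes = 6)
  expect_error(detectHABs(short), "14 days")
  const <- ActivitySeries(rep(5, 240 * 20), binMinutes = 6)
  expect_error(detectHABs(const), "IQR")
})

test_that("HAB calls are invariant to count rescaling, ordered, disjoint", {
  sim <- simulateActivity(nDays = 90, episodes = list(
    habSpec(onsetDay = 20, onsetHour = 16, durationHours = 9,
            amplitude = 5),
    habSpec(onsetDay = 60, onsetHour = 10, durationHours = 18,
            amplitude = 6)), seed = 77)
  calls <- detectHABs(sim$series)
  expect_equal(nrow(calls), 2)
  scaled <- ActivitySeries(counts(sim$series) * 7, binMinutes = 6)
  calls7 <- detectHABs(scaled)
  expect_equal(calls7$start_bin, calls$start_bin)
  expect_equal(calls7$end_bin, calls$end_bin)
  expect_equal(calls7$score, calls$score, tolerance = 1e-10)
  # ordered and non-overlapping
  expect_true(all(diff(calls$start_bin) > 0))
  expect_true(all(head(calls$end_bin, -1) <= tail(calls$start_bin, -1)))
})

test_that("a 21-day 60% reduction is called as one hypoactivity episode", {
  sim <- simulateActivity(nDays = 120, episodes = list(
    deSpec(onsetDay = 40, durationDays = 21, amplitude = 0.4)), seed = 5)
  calls <- detectHypoactivityEpisodes(sim$series)
  expect_equal(nrow(calls), 1)
  covered <- length(intersect(calls$start_day:(calls$end_day - 1),
                              sim$truth$start_day:(sim$truth$end_day - 1)))
  expect_gte(covered / 21, 0.8)
  expect_gte(calls$duration_days, 14)
  expect_gt(calls$score, 0.3)
})

test_that("short reductions and stable series yield no episode calls", {
  # 7-day dip fails the two-week floor
  base <- simulateActivity(nDays = 120, seed = 9)
  x <- counts(base$series)
  bpd <- binsPerDay(base$series)
  dayRate <- rep(c(rep(3, 120), rep(20, 120)))
  set.seed(2)
  x[(39 * bpd + 1):(46 * bpd)] <-
    rnbinom(7 * bpd, mu = rep(0.4 * dayRate, 7), size = 8)
  expect_equal(
    nrow(detectHypoactivityEpisodes(ActivitySeries(x, binMinutes = 6))), 0)

  const <- ActivitySeries(rep(5, 240 * 60), binMinutes = 6)
  expect_equal(nrow(detectHypoactivityEpisodes(const)), 0)
  expect_error(
    detectHypoactivityEpisodes(ActivitySeries(rpois(240 * 30, 5),
                                              binMinutes = 6)),
    "8 weeks")
  expect_error(
    detectHypoactivityEpisodes(ActivitySeries(rep(0, 240 * 60),
                                              binMinutes = 6)),
    "baseline")
})

test_that("delayed activity rises during a simulated episode", {
  sim <- simulateActivity(nDays = 120, episodes = list(
    deSpec(onsetDay = 45, durationDays = 21, amplitude = 0.5,
           lightRedistribution = 0.35)), seed = 14)
  during <- delayedActivityIndex(sim$series, 45:65)
  before <- delayedActivityIndex(sim$series, 31:44)
  after <- delayedActivityIndex(sim$series, 66:79)
  expect_gt(during, before)
  expect_gt(during, after)
})
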