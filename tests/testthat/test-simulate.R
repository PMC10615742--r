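test_that("the activity simulator is deterministic under a fixed seed", {
  a <- simulateActivity(nDays = 10, seed = 123)
  b <- simulateActivity(nDays = 10, seed = 123)
  expect_identical(counts(a$series), counts(b$series))
  c <- simulateActivity(nDays = 10, seed = 124)
  expect_false(identical(counts(a$series), counts(c$series)))
})

test_that("long-run phase means converge to the configured rates", {
  sim <- simulateActivity(nDays = 183, seed = 31)
  x <- counts(sim$series)
  bpd <- binsPerDay(sim$series)
  phase <- rep(rep(c("light", "dark"), each = bpd / 2), 183)
  darkMean <- mean(x[phase == "dark"])
  expect_lt(abs(darkMean - 20) / 20, 0.05)
  lightMean <- mean(x[phase == "light"])
  expect_lt(abs(lightMean - 3) / 3, 0.05)
})

test_that("an injected bout multiplies the nocturnal rate as specified", {
  # 12-h bout covering the dark phase: summed counts ~ 5x the
  # phase-matched baseline expectation
  sim <- simulateActivity(nDays = 30, episodes = list(
    habSpec(onsetDay = 10, onsetHour = 12, durationHours = 12,
            amplitude = 5)), seed = 77)
  x <- counts(sim$series)
  win <- sim$truth$start_bin:(sim$truth$end_bin - 1)
  expected <- 5 * 20 * length(win)  # amplitude x dark rate x bins
  expect_lt(abs(sum(x[win]) - expected) / expected, 0.1)
})

test_that("overlapping same-kind episode specs are rejected", {
  expect_error(simulateActivity(nDays = 60, episodes = list(
    habSpec(onsetDay = 10, onsetHour = 12, durationHours = 12),
    habSpec(onsetDay = 10, onsetHour = 16, durationHours = 12)), seed = 1),
    "overlapping")
  expect_error(simulateActivity(nDays = 90, episodes = list(
    deSpec(onsetDay = 10, durationDays = 21),
    deSpec(onsetDay = 20, durationDays = 21)), seed = 1),
    "overlapping")
  # different kinds may coexist
  sim <- simulateActivity(nDays = 90, episodes = list(
    deSpec(onsetDay = 30, durationDays = 21),
    habSpec(onsetDay = 70, onsetHour = 12, durationHours = 12)), seed = 1)
  expect_equal(nrow(sim$truth), 2)
})

test_that("episode spec validation enforces the duration bounds", {
  expect_error(habSpec(1, 0, durationHours = 3), "\\[6, 24\\]")
  expect_error(deSpec(1, durationDays = 7), "14 days")
  expect_error(deSpec(1, amplitude = 1.2), "\\(0, 1\\)")
})

test_that("detectors also pass under the cosine circadian waveform", {
  sim <- simulateActivity(nDays = 90, waveform = "cosine", episodes = list(
    habSpec(onsetDay = 30, onsetHour = 15, durationHours = 12,
            amplitude = 5)), seed = 99)
  calls <- detectHABs(sim$series)
  expect_equal(nrow(calls), 1)
  expect_gte(jaccardInterval(calls$start_bin, calls$end_bin,
                             sim$truth$start_bin, sim$truth$end_bin), 0.7)
})

test_that("the lipid simulator respects composition and is deterministic", {
  a <- simulateLipidomics(seed = 5)
  b <- simulateLipidomics(seed = 5)
  expect_identical(SummarizedExperiment::assay(a$table),
                   SummarizedExperiment::assay(b$table))
  tab <- table(lipidClass(a$table))
  want <- defaultLipidClassCounts(464)
  expect_equal(as.integer(tab[names(want)]), unname(want))
  expect_equal(nrow(a$table), 464)
  expect_equal(ncol(a$table), 16)
  expect_error(simulateLipidomics(effects = list(
    list(target = "class:NOPE", d = 1)), seed = 1), "not present")
})

test_that("fixture bundles round-trip and regenerate identically", {
  tmp <- withr::local_tempdir()
  cfgs <- list(
    m1 = list(nDays = 20, seed = 11, episodes = list(
      habSpec(onsetDay = 5, onsetHour = 14, durationHours = 12))),
    m2 = list(nDays = 20, seed = 12))
  man <- writeFixtureBundle(cfgs, lipidConfig = list(
    nLipids = 50, groupSizes = c(4, 4), seed = 13), outDir = tmp)
  expect_equal(man$activity$m1$n_episodes, 1)
  s <- readActivityCSV(file.path(tmp, "m1.csv"))
  expect_equal(nDays(s), 20)
  lt <- readLipidTable(file.path(tmp, "lipids", "abundance.tsv"),
                       file.path(tmp, "lipids", "annotation.tsv"),
                       file.path(tmp, "lipids", "samples.tsv"))
  expect_equal(nrow(lt), 50)

  tmp2 <- withr::local_tempdir()
  writeFixtureBundle(cfgs, lipidConfig = list(
    nLipids = 50, groupSizes = c(4, 4), seed = 13), outDir = tmp2)
  for (f in c("m1.csv", "m2.csv", file.path("lipids", "abundance.tsv"))) {
    expect_identical(readLines(file.path(tmp, f)),
                     readLines(file.path(tmp2, f)))
  }
})
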