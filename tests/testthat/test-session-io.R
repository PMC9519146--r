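test_that("trial CSV round trips are lossless and idempotent", {
  tt <- TrialTable(1:3, onset = c(1, 5, 9), offset = c(2, 6.5, 10.1),
                   rewarded = c(FALSE, TRUE, FALSE))
  expect_equal(durations(tt), c(1.0, 1.5, 1.1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeTrials(tt, f1)
  back <- readTrials(f1)
  expect_equal(as.data.frame(back), as.data.frame(tt))
  writeTrials(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty trial table writes a header-only CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrials(TrialTable(), f)
  expect_identical(readLines(f), "trial_id,onset,offset,rewarded")
  expect_equal(nTrials(readTrials(f)), 0L)
})

test_that("trial validation errors cite the offending trial and column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,onset,offset,rewarded",
               "1,1.0,2.0,0", "2,5.0,4.5,1"), f)
  expect_error(readTrials(f), "trial 2")
  writeLines(c("trial_id,onset,rewarded", "1,1.0,0"), f)
  expect_error(readTrials(f), "offset")
  # stored duration disagreeing with offset - onset by > 1 ms
  writeLines(c("trial_id,onset,offset,duration,rewarded",
               "1,1.0,2.0,1.2,0"), f)
  expect_error(readTrials(f), "1 ms")
})

test_that("spike reading validates regions and is row-order invariant", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- c("1,mPFC,r1,0.5", "1,mPFC,r1,1.5", "2,STR,r1,0.2",
            "2,STR,r1,0.9", "2,STR,r1,2.2")
  writeLines(c("unit_id,region,animal,spike_time", rows), f)
  s1 <- readSpikes(f)
  expect_equal(nUnits(s1), 2L)
  expect_equal(spikeTimes(s1, 1), c(0.5, 1.5))
  # shuffled rows give the same set (after a sort warning)
  writeLines(c("unit_id,region,animal,spike_time", rev(rows)), f)
  s2 <- suppressWarnings(readSpikes(f))
  expect_equal(unitInfo(s1), unitInfo(s2))
  expect_equal(s1@spikes, s2@spikes)
  # unknown region is rejected
  writeLines(c("unit_id,region,animal,spike_time", "1,CA1,r1,0.5"), f)
  expect_error(readSpikes(f), "CA1")
})

test_that("spike write/read round trips", {
  sts <- SpikeTrainSet(data.frame(unit_id = c(1L, 2L),
                                  region = c("mPFC", "STR"),
                                  animal = c("r1", "r1")),
                       list(c(0.25, 1.75), c(0.1, 0.2, 3.5)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpikes(sts, f)
  back <- readSpikes(f)
  expect_equal(unitInfo(back), unitInfo(sts))
  expect_equal(back@spikes, sts@spikes)
})

test_that("session validation reports rather than errors", {
  tt <- makeTrials(3)
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "mPFC",
                                  animal = "r1"),
                       list(c(2.1, 2.5, 8.0)))
  rep0 <- validateSession(tt, sts)
  expect_length(rep0$issues, 0)
  expect_equal(rep0$n_trials, 3)
  expect_equal(rep0$units_per_region$mPFC, 1L)
  # spikes entirely after the last trial are flagged
  late <- SpikeTrainSet(unitInfo(sts), list(c(100, 101)))
  expect_gt(length(validateSession(tt, late)$issues), 0)
  # empty spike set: report, not exception
  empty <- SpikeTrainSet(data.frame(unit_id = integer(0),
                                    region = character(0),
                                    animal = character(0)), list())
  repE <- validateSession(tt, empty)
  expect_equal(sum(unlist(repE$units_per_region)), 0L)
})

test_that("manifests link a session's files", {
  dir <- withr::local_tempdir()
  tt <- makeTrials(4)
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "STR",
                                  animal = "r9"), list(c(1, 2, 3)))
  writeTrials(tt, file.path(dir, "t.csv"))
  writeSpikes(sts, file.path(dir, "s.csv"))
  writeSessionManifest(file.path(dir, "m.json"), animal = "r9", day = 2,
                       trialsFile = "t.csv", spikesFile = "s.csv")
  ses <- readSessionManifest(file.path(dir, "m.json"))
  expect_equal(ses$animal, "r9")
  expect_equal(ses$day, 2L)
  expect_equal(nTrials(ses$trials), 4L)
  expect_equal(ses$task@criterion, 1.5)
})

test_that("TrialTable invariants reject malformed tables", {
  expect_error(TrialTable(1:2, c(1, 2), c(2, 1.5), c(FALSE, FALSE)),
               "offset")
  expect_error(TrialTable(1:2, c(1, 1.5), c(2, 3), c(FALSE, FALSE)),
               "overlap")
})
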