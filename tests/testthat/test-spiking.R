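test_that("reinforced-trial selection uses [criterion, cap)", {
  tt <- trialsFromDurations(c(0.8, 1.6, 2.0, 4.0))
  sel <- selectReinforced(tt)
  expect_equal(durations(sel), c(1.6, 2.0))
  # closed lower bound at exactly 1.5 s; exclusive cap at 3.5 s
  tt2 <- trialsFromDurations(c(1.5, 3.5))
  expect_equal(durations(selectReinforced(tt2)), 1.5)
  # all premature: empty selection with a warning
  expect_warning(sel0 <- selectReinforced(trialsFromDurations(c(0.5, 1.0))),
                 "empty")
  expect_equal(nTrials(sel0), 0L)
})

test_that("epoching re-references times to the alignment event", {
  tt <- TrialTable(1L, onset = 10.0, offset = 11.0, rewarded = FALSE)
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "mPFC",
                                  animal = "r1"),
                       list(c(9.2, 9.6, 10.2, 11.5)))
  on <- epochTrials(sts, tt, "onset")
  # 9.2 is before onset - 0.5 and 11.5 after offset: both excluded
  expect_equal(on@times[[1]][[1]], c(-0.4, 0.2))
  off <- epochTrials(sts, tt, "offset")
  expect_equal(off@times[[1]][[1]], c(-1.4, -0.8))
  expect_true(all(off@times[[1]][[1]] <= 0))
})

test_that("overlapping epochs warn and share spikes", {
  tt <- TrialTable(1:2, onset = c(1.0, 2.2), offset = c(2.0, 3.0),
                   rewarded = c(FALSE, FALSE))
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "STR",
                                  animal = "r1"), list(1.9))
  expect_warning(ep <- epochTrials(sts, tt, "onset"), "overlap")
  expect_equal(ep@times[[1]][[1]], 0.9)    # inside trial 1
  expect_equal(ep@times[[2]][[1]], -0.3)   # inside trial 2's pre-onset
})

test_that("kernel smoothing conserves spike mass inside the window", {
  tt <- makeTrials(1, dur = 1.6)
  onset <- as.data.frame(tt)$onset[1]
  # spikes at interior and window-edge positions
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "mPFC",
                                  animal = "r1"),
                       list(onset + c(0.02, 0.75, 1.49)))
  rt <- rateTensor(epochTrials(sts, tt, "onset"), c(0, 1.5))
  expect_equal(sum(rt@values[1, 1, ]) * rt@binWidth, 3, tolerance = 1e-9)
  # zero spikes give an all-zero tensor
  empty <- SpikeTrainSet(unitInfo(sts), list(numeric(0)))
  rt0 <- rateTensor(epochTrials(empty, tt, "onset"), c(0, 1.5))
  expect_true(all(rt0@values == 0))
})

test_that("rate tensors are linear in spike trains", {
  tt <- makeTrials(5, dur = 1.8)
  tr <- as.data.frame(tt)
  set.seed(13)
  mkSpikes <- function() sort(unlist(lapply(seq_len(5), function(j)
    runif(8, tr$onset[j] - 0.4, tr$offset[j]))))
  a <- mkSpikes(); b <- mkSpikes()
  units <- data.frame(unit_id = 1L, region = "mPFC", animal = "r1")
  rtA <- rateTensor(epochTrials(SpikeTrainSet(units, list(a)), tt, "onset"),
                    c(0, 1.5))
  rtB <- rateTensor(epochTrials(SpikeTrainSet(units, list(b)), tt, "onset"),
                    c(0, 1.5))
  merged <- rateTensor(epochTrials(SpikeTrainSet(units, list(sort(c(a, b)))),
                                   tt, "onset"), c(0, 1.5))
  expect_equal(merged@values, rtA@values + rtB@values, tolerance = 1e-9)
})

test_that("a homogeneous Poisson unit recovers its rate", {
  tt <- makeTrials(200, dur = 1.8)
  cfg <- populationGenConfig(archetypeConfig("untuned", baselineRate = 10),
                             counts = 1, animal = "r1", seed = 17)
  rt <- animalRateTensor(tt, cfg)
  grand <- mean(rt@values)
  # SE of the grand mean rate from Poisson counts over the whole window
  se <- sqrt(10 / (200 * 1.5))
  expect_lt(abs(grand - 10), 3 * se)
})

test_that("windows outside the epoch are rejected", {
  tt <- makeTrials(3, dur = 1.2)  # shorter than the 1.5 s window
  sts <- SpikeTrainSet(data.frame(unit_id = 1L, region = "mPFC",
                                  animal = "r1"), list(numeric(0)))
  ep <- epochTrials(sts, tt, "onset")
  expect_error(rateTensor(ep, c(0, 1.5)), "outside the epoch")
  expect_error(rateTensor(ep, c(0, 1.23)), "integer number")
})

test_that("climbing detection flags exact ramps and spares constants", {
  edges <- seq(0, 1.5, by = 0.1)
  centers <- (edges[-1] + edges[-16]) / 2
  mk <- function(y) {
    vals <- array(rep(y, each = 4), dim = c(4, 1, 15))
    new("RateTensor", values = vals, binEdges = edges, binWidth = 0.1,
        kernelSigma = 0, alignment = "onset", trialIds = 1:4,
        units = data.frame(unit_id = 1L, region = "mPFC", animal = "r1"))
  }
  up <- detectClimbing(mk(5 + 4 * centers))
  expect_true(up$flagged)
  expect_equal(up$slope, 4, tolerance = 1e-9)
  down <- detectClimbing(mk(10 - 3 * centers))
  expect_true(down$flagged)
  expect_lt(down$slope, 0)
  flat <- detectClimbing(mk(rep(10, 15)))
  expect_false(flat$flagged)
  expect_equal(flat$p, 1)
  zero <- detectClimbing(mk(rep(0, 15)))
  expect_equal(zero$slope, 0)
  expect_equal(zero$p, 1)
})

test_that("waveform stability applies the SD-band rule sample-wise", {
  base <- sin(seq(0, 2 * pi, length.out = 30))
  sd <- rep(0.2, 30)
  expect_true(waveformStable(WaveformPair(base, sd, base)))
  drift <- base; drift[12] <- base[12] + 2 * sd[12]
  expect_false(waveformStable(WaveformPair(base, sd, drift)))
  # closed interval: zero SD with identical means is stable
  expect_true(waveformStable(WaveformPair(base, rep(0, 30), base)))
  expect_error(WaveformPair(base, sd, base[-1]), "equal lengths")
})
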