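# Fixtures built in code: deterministic trial tables and small sessions.

# n identical trials of fixed duration, evenly spaced
makeTrials <- function(n, dur = 1.8, gap = 2, rewardedAt = 1.5) {
  onset <- (seq_len(n) - 1) * (dur + gap) + gap
  TrialTable(seq_len(n), onset, onset + dur, rep(dur >= rewardedAt, n))
}

# trial table with explicit durations
trialsFromDurations <- function(dur, gap = 2, criterion = 1.5) {
  onset <- cumsum(c(gap, dur[-length(dur)] + gap))
  TrialTable(seq_along(dur), onset, onset + dur, dur >= criterion)
}

# archetype set tiling the decoded window with time cells
tilingTimeCells <- function(n = 20, from = 0.25, to = 1.15,
                            baseline = 2, peak = 20, width = 0.15) {
  lapply(seq(from, to, length.out = n), function(pt)
    archetypeConfig("time_cell", baselineRate = baseline, peakRate = peak,
                    preferredTime = pt, tuningWidth = width))
}

# rate tensor for one simulated animal over its reinforced trials
animalRateTensor <- function(trials, popConfig, task = TaskConfig(),
                             window = c(0, 1.5)) {
  re <- selectReinforced(trials, task)
  sp <- simulatePopulation(re, popConfig, preOnset = task@preOnset)
  ep <- suppressWarnings(epochTrials(sp, re, "onset", task))
  rateTensor(ep, window, task)
}
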