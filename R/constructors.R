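#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a trial table
#'
#' @param trial_id positive integer ids, strictly increasing.
#' @param onset,offset trial bounds, seconds from session start.
#' @param rewarded logical reward flags.
#' @return a [TrialTable-class]; `duration` is computed as `offset - onset`.
#' @examples
#' TrialTable(1:2, onset = c(1, 5), offset = c(2, 6.5),
#'            rewarded = c(FALSE, TRUE))
#' @export
TrialTable <- function(trial_id = integer(0), onset = numeric(0),
                       offset = numeric(0), rewarded = logical(0)) {
  tr <- data.frame(trial_id = as.integer(trial_id),
                   onset = as.numeric(onset),
                   offset = as.numeric(offset),
                   duration = as.numeric(offset) - as.numeric(onset),
                   rewarded = as.logical(rewarded))
  new("TrialTable", trials = tr)
}

#' Construct a task configuration
#'
#' @param criterion reinforcement criterion in seconds (default 1.5).
#' @param upperCap exclusive upper duration cap for decoded trials (3.5).
#' @param preOnset pre-onset epoch length in seconds (0.5).
#' @param binWidth rate bin width in seconds (0.1).
#' @param kernelSigma smoothing kernel SD in seconds (0.1).
#' @return a [TaskConfig-class]
#' @export
TaskConfig <- function(criterion = 1.5, upperCap = 3.5, preOnset = 0.5,
                       binWidth = 0.1, kernelSigma = 0.1) {
  new("TaskConfig", criterion = criterion, upperCap = upperCap,
      preOnset = preOnset, binWidth = binWidth, kernelSigma = kernelSigma)
}

#' Construct a spike-train set
#'
#' @param units data.frame with columns `unit_id`, `region`, `animal`.
#' @param spikes list of ascending numeric spike-time vectors (seconds),
#'   parallel to `units`.
#' @return a [SpikeTrainSet-class]
#' @export
SpikeTrainSet <- function(units, spikes) {
  units$region <- as.character(units$region)
  units$animal <- as.character(units$animal)
  new("SpikeTrainSet", units = as.data.frame(units), spikes = spikes)
}

#' Construct a waveform stability pair
#'
#' @param startMean,startSd mean and SD of the session-start waveforms (uV).
#' @param endMean mean of the session-end waveforms (uV).
#' @return a [WaveformPair-class]
#' @export
WaveformPair <- function(startMean, startSd, endMean) {
  new("WaveformPair", startMean = as.numeric(startMean),
      startSd = as.numeric(startSd), endMean = as.numeric(endMean))
}

#' Construct double-Gaussian parameters
#'
#' @param gamma amplitude ratio of the timed mode, in \[0, 1\].
#' @param mu1,sigma1 premature-mode mean and SD (seconds).
#' @param mu2,sigma2 timed-mode mean and SD (seconds), `mu1 <= mu2`.
#' @return a [DoubleGaussParams-class]
#' @examples
#' DoubleGaussParams(0.5, 0.2, 0.1, 1.0, 0.5)
#' @export
DoubleGaussParams <- function(gamma, mu1, sigma1, mu2, sigma2) {
  new("DoubleGaussParams", gamma = gamma, mu1 = mu1, sigma1 = sigma1,
      mu2 = mu2, sigma2 = sigma2)
}

#' Construct a decoder configuration
#'
#' Defaults follow the analysis conventions: 1000 random folds, 80% of
#' pseudo-trials for training, 10 decoded classes obtained by dropping the
#' first 2 and last 3 of the 15 bins covering the truncated trial (0-1.5 s),
#' so decoding spans 0.2-1.2 s after onset.
#'
#' @param nFolds number of random folds.
#' @param trainFraction training fraction of pseudo-trials.
#' @param nClasses number of decoded classes K.
#' @param dropFirst,dropLast head/tail bins removed before decoding.
#' @param seed RNG seed for fold draws.
#' @return a [DecoderConfig-class]
#' @export
DecoderConfig <- function(nFolds = 1000, trainFraction = 0.8, nClasses = 10,
                          dropFirst = 2, dropLast = 3, seed = 1) {
  new("DecoderConfig", nFolds = as.integer(nFolds),
      trainFraction = trainFraction, nClasses = as.integer(nClasses),
      dropFirst = as.integer(dropFirst), dropLast = as.integer(dropLast),
      seed = as.integer(seed))
}

#' Construct a behavioural-session generator configuration
#'
#' The defaults emulate a naive animal acquiring the 1.5 s criterion within
#' a single session: the session starts dominated by premature responses
#' (gamma = 0.04) and ends dominated by temporally controlled responses
#' (gamma = 0.90, timed mode near 2 s) while remaining bimodal. With linear
#' interpolation these defaults put the mean hold duration of the first
#' session half near 1.0 s and of the second half near 1.7 s, the group
#' behaviour typical of single-session acquisition in this task.
#'
#' @param nTrials number of trials (default 600, a typical single session).
#' @param startParams,endParams [DoubleGaussParams-class] at session
#'   start/end.
#' @param interpolation "linear" (default) or "logistic" over trial index.
#' @param meanIti mean exponential inter-trial interval, seconds (2).
#' @param seed integer RNG seed.
#' @return a [BehaviorGenConfig-class]
#' @export
behaviorGenConfig <- function(nTrials = 600,
                              startParams = DoubleGaussParams(0.04, 0.30, 0.15, 1.5, 0.5),
                              endParams = DoubleGaussParams(0.90, 0.28, 0.12, 2.05, 0.45),
                              interpolation = "linear", meanIti = 2,
                              seed = 1) {
  new("BehaviorGenConfig", nTrials = as.integer(nTrials),
      startParams = startParams, endParams = endParams,
      interpolation = interpolation, meanIti = meanIti,
      seed = as.integer(seed))
}

#' Construct a single-unit response archetype
#'
#' @param kind one of "time_cell", "ramp_up", "ramp_down", "onset_locked",
#'   "offset_locked", "untuned".
#' @param baselineRate baseline firing rate, Hz (default 2).
#' @param peakRate peak rate of bump-like archetypes, Hz (default 20).
#' @param preferredTime preferred latency of a time cell, seconds.
#' @param tuningWidth bump SD, seconds (default 0.15).
#' @param slope ramp slope, Hz/s (default 4; use negative for ramp_down).
#' @return an [ArchetypeConfig-class]
#' @export
archetypeConfig <- function(kind, baselineRate = 2, peakRate = 20,
                            preferredTime = 0.75, tuningWidth = 0.15,
                            slope = if (identical(kind, "ramp_down")) -4 else 4) {
  new("ArchetypeConfig", kind = kind, baselineRate = baselineRate,
      peakRate = peakRate, preferredTime = preferredTime,
      tuningWidth = tuningWidth, slope = slope)
}

#' Construct a population generator configuration
#'
#' @param archetypes list of [ArchetypeConfig-class].
#' @param counts units per archetype.
#' @param strengthEarly,strengthLate per-stage encoding strength in \[0, 1\].
#' @param region "mPFC" or "STR".
#' @param animal animal id label.
#' @param seed integer RNG seed.
#' @return a [PopulationGenConfig-class]
#' @export
populationGenConfig <- function(archetypes, counts, strengthEarly = 1,
                                strengthLate = 1, region = "mPFC",
                                animal = "rat1", seed = 1) {
  if (inherits(archetypes, "ArchetypeConfig")) archetypes <- list(archetypes)
  new("PopulationGenConfig", archetypes = archetypes,
      counts = as.integer(counts), strengthEarly = strengthEarly,
      strengthLate = strengthLate, region = region,
      animal = as.character(animal), seed = as.integer(seed))
}
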