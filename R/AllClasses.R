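#' @import methods
NULL

## Central S4 containers for the pipeline. Times are always seconds from
## session start (behaviour) or seconds relative to an alignment event
## (epoched spikes); no integer tick representation is used anywhere.

#' Behavioural trial table
#'
#' One behavioural session: ordered, non-overlapping trials, each defined by
#' the nose-poke (or lever) onset and offset, the response duration
#' (offset - onset) and whether the response met the reinforcement criterion.
#'
#' @slot trials data.frame with columns `trial_id` (positive integer,
#'   strictly increasing), `onset`, `offset`, `duration` (seconds) and
#'   `rewarded` (logical).
#'
#' @export
setClass("TrialTable", representation(trials = "data.frame"))

setValidity("TrialTable", function(object) {
  tr <- object@trials
  need <- c("trial_id", "onset", "offset", "duration", "rewarded")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(tr) == 0) return(TRUE)
  if (any(!is.finite(tr$onset)) || any(!is.finite(tr$offset)))
    return("onset/offset must be finite")
  bad <- which(tr$offset <= tr$onset)
  if (length(bad) > 0)
    return(sprintf("offset <= onset for trial %d", tr$trial_id[bad[1]]))
  if (any(tr$duration < 0)) return("negative duration")
  if (max(abs(tr$duration - (tr$offset - tr$onset))) > 1e-3)
    return("duration inconsistent with offset - onset (> 1 ms)")
  if (is.unsorted(tr$onset)) return("trials must be sorted by onset")
  if (any(diff(tr$trial_id) <= 0) || any(tr$trial_id <= 0))
    return("trial_id must be positive and strictly increasing")
  if (nrow(tr) > 1 && any(tr$onset[-1] < tr$offset[-nrow(tr)]))
    return("trial intervals overlap")
  if (!is.logical(tr$rewarded)) return("rewarded must be logical")
  TRUE
})

#' Task configuration
#'
#' Timing-task parameters: the reinforcement criterion (minimum hold
#' duration that is rewarded), the upper duration cap used when selecting
#' trials for decoding, the pre-onset epoch length, and the rate-estimation
#' bin width and Gaussian kernel width.
#'
#' @slot criterion seconds; reinforced when duration >= criterion (1.5).
#' @slot upperCap seconds; decoding uses trials with duration < upperCap (3.5).
#' @slot preOnset seconds of activity kept before trial onset (0.5).
#' @slot binWidth rate bin width in seconds (0.1).
#' @slot kernelSigma Gaussian smoothing kernel SD in seconds (0.1).
#'
#' @export
setClass("TaskConfig",
         representation(criterion = "numeric", upperCap = "numeric",
                        preOnset = "numeric", binWidth = "numeric",
                        kernelSigma = "numeric"),
         prototype(criterion = 1.5, upperCap = 3.5, preOnset = 0.5,
                   binWidth = 0.1, kernelSigma = 0.1))

setValidity("TaskConfig", function(object) {
  v <- c(object@criterion, object@upperCap, object@preOnset, object@binWidth)
  if (any(!is.finite(v)) || any(v <= 0)) return("all fields must be positive")
  if (!is.finite(object@kernelSigma) || object@kernelSigma < 0)
    return("kernelSigma must be >= 0 (0 disables smoothing)")
  if (object@criterion >= object@upperCap) return("criterion must be < upperCap")
  TRUE
})

#' Set of sorted spike trains
#'
#' Sorted units with their spike timestamps plus region and animal labels.
#' Regions are restricted to the two recorded areas, medial prefrontal
#' cortex ("mPFC") and dorsal striatum ("STR").
#'
#' @slot units data.frame with columns `unit_id`, `region`, `animal`.
#' @slot spikes list of numeric vectors (seconds, ascending), parallel to
#'   the rows of `units`.
#'
#' @export
setClass("SpikeTrainSet",
         representation(units = "data.frame", spikes = "list"))

.VALID_REGIONS <- c("mPFC", "STR")

setValidity("SpikeTrainSet", function(object) {
  u <- object@units
  need <- c("unit_id", "region", "animal")
  miss <- setdiff(need, names(u))
  if (length(miss) > 0)
    return(sprintf("missing unit column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(u) != length(object@spikes))
    return("units table and spikes list lengths differ")
  bad <- setdiff(unique(u$region), .VALID_REGIONS)
  if (length(bad) > 0)
    return(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
  for (i in seq_along(object@spikes)) {
    s <- object@spikes[[i]]
    if (length(s) == 0) next
    if (any(s < 0)) return("negative spike time")
    if (is.unsorted(s, strictly = FALSE)) return("spike times not ascending")
  }
  TRUE
})

#' Waveform stability pair
#'
#' Mean spike waveform (and its SD band) from the beginning of a session
#' together with the mean waveform at the end, used for the
#' stability-screening rule.
#'
#' @slot startMean,startSd,endMean equal-length numeric sample vectors (uV).
#'
#' @export
setClass("WaveformPair",
         representation(startMean = "numeric", startSd = "numeric",
                        endMean = "numeric"))

setValidity("WaveformPair", function(object) {
  n <- length(object@startMean)
  if (length(object@startSd) != n || length(object@endMean) != n)
    return("waveform vectors must have equal lengths")
  if (any(object@startSd < 0)) return("startSd must be non-negative")
  TRUE
})

#' Double-Gaussian duration-density parameters
#'
#' The five parameters of the bimodal response-duration density: the
#' premature mode (mu1, sigma1), the temporally controlled mode
#' (mu2, sigma2), and gamma, the amplitude ratio of the second mode in the
#' unnormalised mixture. gamma is an amplitude ratio, not a mixture weight
#' of normalised components (the two differ because the modes are
#' unnormalised in the mixture function).
#'
#' @slot gamma amplitude ratio of the second mode, in \[0, 1\].
#' @slot mu1,sigma1 mean and SD of the premature mode (seconds).
#' @slot mu2,sigma2 mean and SD of the timed mode (seconds); mu1 <= mu2.
#'
#' @export
setClass("DoubleGaussParams",
         representation(gamma = "numeric", mu1 = "numeric", sigma1 = "numeric",
                        mu2 = "numeric", sigma2 = "numeric"))

setValidity("DoubleGaussParams", function(object) {
  v <- c(object@gamma, object@mu1, object@sigma1, object@mu2, object@sigma2)
  if (length(v) != 5 || any(!is.finite(v))) return("all 5 parameters must be finite scalars")
  if (object@gamma < 0 || object@gamma > 1) return("gamma must lie in [0, 1]")
  if (object@sigma1 <= 0 || object@sigma2 <= 0) return("sigmas must be positive")
  if (object@mu1 > object@mu2) return("mu1 must be <= mu2")
  TRUE
})

#' Discretely normalised duration density grid
#'
#' The double-Gaussian mixture evaluated on the fixed grid ti = i * 0.1 s,
#' i = 0..60, with its discrete normalisation term and the normalised
#' density p = f / xi, so that sum(p) * 0.1 == 1.
#'
#' @slot t grid points (seconds).
#' @slot f unnormalised mixture values.
#' @slot xi normalisation term, `dt * sum(f)`.
#' @slot p normalised density values.
#' @slot dt grid spacing (0.1 s).
#'
#' @export
setClass("DensityGrid",
         representation(t = "numeric", f = "numeric", xi = "numeric",
                        p = "numeric", dt = "numeric"))

setValidity("DensityGrid", function(object) {
  if (length(object@t) != length(object@f) ||
      length(object@t) != length(object@p))
    return("t, f, p must have equal lengths")
  if (any(object@p < 0)) return("density values must be non-negative")
  if (abs(sum(object@p) * object@dt - 1) > 1e-9)
    return("density must integrate (discretely) to 1")
  TRUE
})

#' Peri-event epoched spike times
#'
#' Spike times cut to the per-trial analysis epoch
#' \[onset - preOnset, offset\] and re-referenced to the alignment event
#' (trial onset or offset). With offset alignment all relative times are
#' <= 0.
#'
#' @slot times list (one element per trial) of lists (one per unit) of
#'   relative spike times.
#' @slot alignment "onset" or "offset".
#' @slot bounds matrix (trials x 2) of epoch bounds in relative time.
#' @slot trialIds integer trial ids.
#' @slot units the unit table carried over from the [SpikeTrainSet-class].
#'
#' @export
setClass("EpochedSpikes",
         representation(times = "list", alignment = "character",
                        bounds = "matrix", trialIds = "integer",
                        units = "data.frame"))

setValidity("EpochedSpikes", function(object) {
  if (!object@alignment %in% c("onset", "offset"))
    return("alignment must be 'onset' or 'offset'")
  if (length(object@times) != length(object@trialIds))
    return("times and trialIds lengths differ")
  TRUE
})

#' Trials x units x time-bins firing-rate tensor
#'
#' Kernel-smoothed firing rates: spikes are convolved with a Gaussian kernel
#' (truncated at +/- 3 SD and renormalised inside the analysis window),
#' integrated over uniform bins and divided by the bin width, giving Hz.
#'
#' @slot values numeric array, trials x units x bins.
#' @slot binEdges bin edges in seconds relative to the alignment event.
#' @slot binWidth,kernelSigma seconds.
#' @slot alignment "onset" or "offset".
#' @slot trialIds integer trial ids.
#' @slot units unit table (unit_id, region, animal).
#'
#' @export
setClass("RateTensor",
         representation(values = "array", binEdges = "numeric",
                        binWidth = "numeric", kernelSigma = "numeric",
                        alignment = "character", trialIds = "integer",
                        units = "data.frame"))

setValidity("RateTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-d array")
  if (d[3] != length(object@binEdges) - 1)
    return("bin count inconsistent with binEdges")
  if (any(object@values < 0)) return("rates must be non-negative")
  w <- diff(object@binEdges)
  if (max(abs(w - object@binWidth)) > 1e-9) return("bins must be uniform")
  TRUE
})

#' Pseudo-population ("average animal") design tensors
#'
#' Units pooled across animals by matching reinforced-trial counts: with N
#' the smallest per-animal reinforced-trial count, every animal contributes
#' its first floor(N/2) reinforced trials to the early stage and its last
#' floor(N/2) to the late stage; pseudo-trial k concatenates the k-th
#' selected trial's unit rates across animals.
#'
#' @slot early,late numeric arrays, pseudo-trials x units x decoded bins.
#' @slot units provenance table (unit_id, region, animal).
#' @slot nMatched the matched trial count N.
#' @slot binTimes centres of the decoded bins (seconds from onset).
#'
#' @export
setClass("PseudoPopulation",
         representation(early = "array", late = "array", units = "data.frame",
                        nMatched = "integer", binTimes = "numeric"))

setValidity("PseudoPopulation", function(object) {
  de <- dim(object@early); dl <- dim(object@late)
  if (length(de) != 3 || length(dl) != 3) return("stage tensors must be 3-d")
  if (!all(de == dl)) return("early and late tensors must match in shape")
  if (de[2] != nrow(object@units)) return("unit dimension mismatch")
  TRUE
})

#' Decoder configuration
#'
#' Cross-validation and class layout for the time-bin decoder.
#'
#' @slot nFolds number of random folds (1000).
#' @slot trainFraction fraction of pseudo-trials used for training (0.8).
#' @slot nClasses number of decoded time bins K (10).
#' @slot dropFirst,dropLast bins removed from the head/tail of the truncated
#'   trial before decoding (2 and 3 of the 15 bins spanning 0-1.5 s, so the
#'   default decoded window is 0.2-1.2 s after onset).
#' @slot seed RNG seed for the fold draws.
#'
#' @export
setClass("DecoderConfig",
         representation(nFolds = "integer", trainFraction = "numeric",
                        nClasses = "integer", dropFirst = "integer",
                        dropLast = "integer", seed = "integer"),
         prototype(nFolds = 1000L, trainFraction = 0.8, nClasses = 10L,
                   dropFirst = 2L, dropLast = 3L, seed = 1L))

setValidity("DecoderConfig", function(object) {
  if (object@nFolds < 1) return("nFolds must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie strictly between 0 and 1")
  if (object@nClasses < 2) return("need at least 2 decoded classes")
  TRUE
})

#' Decoding result
#'
#' Fold-averaged confusion matrix (rows: actual time bin; entries: mean
#' predicted-class probability, each row summing to 1) together with the
#' per-fold Pearson-R distribution and its summary.
#'
#' @slot confusion K x K matrix.
#' @slot foldR per-fold Pearson correlations between actual and predicted bin.
#' @slot meanR,sdR mean and SD of the fold-R distribution.
#' @slot ciMean 2.5-97.5 bootstrap percentile interval of the mean R.
#' @slot nFolds,nTrials,nUnits problem dimensions.
#'
#' @export
setClass("DecodeResult",
         representation(confusion = "matrix", foldR = "numeric",
                        meanR = "numeric", sdR = "numeric", ciMean = "numeric",
                        nFolds = "integer", nTrials = "integer",
                        nUnits = "integer"))

setValidity("DecodeResult", function(object) {
  rs <- rowSums(object@confusion)
  if (max(abs(rs - 1)) > 1e-9) return("confusion rows must sum to 1")
  if (any(object@foldR < -1 - 1e-12 | object@foldR > 1 + 1e-12))
    return("fold R values must lie in [-1, 1]")
  TRUE
})

#' Jackknife leave-one-animal-out comparison result
#'
#' Leave-one-out differences of a statistic between two conditions, the raw
#' one-sample t over those differences, and the corrected t (raw t divided
#' by N - 1) with its two-sided p-value.
#'
#' @slot values per-run A - B differences (one per omitted animal).
#' @slot rawT,correctedT t statistics; |correctedT| <= |rawT|.
#' @slot df degrees of freedom used for the p-value (N - 1).
#' @slot p two-sided p-value of the corrected t.
#'
#' @export
setClass("JackknifeResult",
         representation(values = "numeric", rawT = "numeric",
                        correctedT = "numeric", df = "numeric", p = "numeric"))

setValidity("JackknifeResult", function(object) {
  if (length(object@values) < 3) return("need at least 3 leave-one-out runs")
  if (abs(object@correctedT) > abs(object@rawT) + 1e-12)
    return("|correctedT| must not exceed |rawT|")
  TRUE
})

## ---- generator configuration classes -------------------------------------

#' Behavioural-session generator configuration
#'
#' Emulates within-session timing acquisition: hold durations are drawn from
#' a double-Gaussian mixture whose parameters interpolate from `startParams`
#' (naive) to `endParams` (proficient) across the trial index, so the
#' duration distribution shifts to the right as in single-session learning.
#'
#' @slot nTrials number of trials (>= 2).
#' @slot startParams,endParams [DoubleGaussParams-class] at session start/end.
#' @slot interpolation "linear" or "logistic" over the trial index.
#' @slot meanIti mean of the exponential inter-trial interval (seconds).
#' @slot seed integer RNG seed.
#'
#' @export
setClass("BehaviorGenConfig",
         representation(nTrials = "integer", startParams = "DoubleGaussParams",
                        endParams = "DoubleGaussParams",
                        interpolation = "character", meanIti = "numeric",
                        seed = "integer"))

setValidity("BehaviorGenConfig", function(object) {
  if (object@nTrials < 2) return("nTrials must be >= 2")
  if (!object@interpolation %in% c("linear", "logistic"))
    return("interpolation must be 'linear' or 'logistic'")
  if (!is.finite(object@meanIti) || object@meanIti <= 0)
    return("meanIti must be positive")
  TRUE
})

#' Single-unit response archetype
#'
#' Parametric within-trial rate profiles emulating the response classes seen
#' in the recordings: time cells (a Gaussian bump at a preferred latency),
#' up/down ramps, onset- or offset-locked bumps, and untuned units.
#'
#' @slot kind one of "time_cell", "ramp_up", "ramp_down", "onset_locked",
#'   "offset_locked", "untuned".
#' @slot baselineRate,peakRate Hz.
#' @slot preferredTime seconds (time cells).
#' @slot tuningWidth seconds (bump SD).
#' @slot slope Hz/s (ramps; negative for ramp_down).
#'
#' @export
setClass("ArchetypeConfig",
         representation(kind = "character", baselineRate = "numeric",
                        peakRate = "numeric", preferredTime = "numeric",
                        tuningWidth = "numeric", slope = "numeric"))

.ARCHETYPE_KINDS <- c("time_cell", "ramp_up", "ramp_down",
                      "onset_locked", "offset_locked", "untuned")

setValidity("ArchetypeConfig", function(object) {
  if (!object@kind %in% .ARCHETYPE_KINDS)
    return(sprintf("unknown archetype kind '%s'", object@kind))
  if (object@baselineRate < 0 || object@peakRate < 0)
    return("rates must be non-negative")
  if (object@tuningWidth <= 0) return("tuningWidth must be positive")
  TRUE
})

#' Population generator configuration
#'
#' A mixture of archetypes for one region of one animal, with a per-stage
#' encoding-strength knob in \[0, 1\] that scales the modulation depth of
#' every unit toward its baseline (0 = untuned, 1 = full modulation). The
#' early strength applies to the first half of the session's trials and the
#' late strength to the second half.
#'
#' @slot archetypes list of [ArchetypeConfig-class].
#' @slot counts integer vector, units per archetype.
#' @slot strengthEarly,strengthLate encoding strength per stage, in \[0, 1\].
#' @slot region "mPFC" or "STR".
#' @slot animal animal id label.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("PopulationGenConfig",
         representation(archetypes = "list", counts = "integer",
                        strengthEarly = "numeric", strengthLate = "numeric",
                        region = "character", animal = "character",
                        seed = "integer"))

setValidity("PopulationGenConfig", function(object) {
  if (length(object@archetypes) == 0) return("archetype mixture is empty")
  if (length(object@counts) != length(object@archetypes))
    return("counts and archetypes lengths differ")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (sum(object@counts) == 0) return("archetype mixture has zero total units")
  s <- c(object@strengthEarly, object@strengthLate)
  if (any(s < 0 | s > 1)) return("encoding strength must lie in [0, 1]")
  if (!object@region %in% .VALID_REGIONS)
    return(sprintf("unknown region label '%s'", object@region))
  TRUE
})
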