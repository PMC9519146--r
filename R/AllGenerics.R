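#' @include AllClasses.R
NULL

#' Number of trials
#' @param x a [TrialTable-class] or [RateTensor-class]
#' @return integer count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of units
#' @param x a [SpikeTrainSet-class], [RateTensor-class] or
#'   [PseudoPopulation-class]
#' @return integer count
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Trial durations in seconds
#' @param x a [TrialTable-class]
#' @return numeric vector
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' Reward flags
#' @param x a [TrialTable-class]
#' @return logical vector
#' @export
setGeneric("rewarded", function(x) standardGeneric("rewarded"))

#' Unit metadata table (unit_id, region, animal)
#' @param x a [SpikeTrainSet-class], [RateTensor-class] or
#'   [PseudoPopulation-class]
#' @return data.frame
#' @export
setGeneric("unitInfo", function(x) standardGeneric("unitInfo"))

#' Spike times of one unit
#' @param x a [SpikeTrainSet-class]
#' @param i unit index
#' @return numeric vector of seconds
#' @export
setGeneric("spikeTimes", function(x, i) standardGeneric("spikeTimes"))

#' Fold-averaged confusion matrix
#' @param x a [DecodeResult-class]
#' @return K x K matrix, rows = actual bin, summing to 1
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' Per-fold Pearson-R values
#' @param x a [DecodeResult-class]
#' @return numeric vector
#' @export
setGeneric("foldR", function(x) standardGeneric("foldR"))

#' Mean decoder performance (Pearson R)
#' @param x a [DecodeResult-class]
#' @return numeric scalar
#' @export
setGeneric("meanR", function(x) standardGeneric("meanR"))

#' Extract a stage design tensor from a pseudo-population
#' @param x a [PseudoPopulation-class]
#' @param stage "early" or "late"
#' @return numeric array, pseudo-trials x units x decoded bins
#' @export
setGeneric("stageTensor", function(x, stage) standardGeneric("stageTensor"))
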