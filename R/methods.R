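#' @include AllClasses.R AllGenerics.R
NULL

## accessors -----------------------------------------------------------------

#' @describeIn TrialTable-class number of trials
#' @param x object
#' @export
setMethod("nTrials", "TrialTable", function(x) nrow(x@trials))

#' @describeIn RateTensor-class number of trials
#' @param x object
#' @export
setMethod("nTrials", "RateTensor", function(x) dim(x@values)[1])

#' @describeIn TrialTable-class response durations (seconds)
#' @export
setMethod("durations", "TrialTable", function(x) x@trials$duration)

#' @describeIn TrialTable-class logical reward flags
#' @export
setMethod("rewarded", "TrialTable", function(x) x@trials$rewarded)

#' @describeIn SpikeTrainSet-class number of units
#' @param x object
#' @export
setMethod("nUnits", "SpikeTrainSet", function(x) nrow(x@units))

#' @describeIn RateTensor-class number of units
#' @export
setMethod("nUnits", "RateTensor", function(x) dim(x@values)[2])

#' @describeIn PseudoPopulation-class number of pooled units
#' @param x object
#' @export
setMethod("nUnits", "PseudoPopulation", function(x) nrow(x@units))

#' @describeIn SpikeTrainSet-class unit metadata
#' @export
setMethod("unitInfo", "SpikeTrainSet", function(x) x@units)

#' @describeIn RateTensor-class unit metadata
#' @export
setMethod("unitInfo", "RateTensor", function(x) x@units)

#' @describeIn PseudoPopulation-class unit provenance
#' @export
setMethod("unitInfo", "PseudoPopulation", function(x) x@units)

#' @describeIn SpikeTrainSet-class spike times of unit `i`
#' @param i unit index
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x, i) x@spikes[[i]])

#' @describeIn DecodeResult-class fold-averaged confusion matrix
#' @param x object
#' @export
setMethod("confusionMatrix", "DecodeResult", function(x) x@confusion)

#' @describeIn DecodeResult-class per-fold Pearson-R values
#' @export
setMethod("foldR", "DecodeResult", function(x) x@foldR)

#' @describeIn DecodeResult-class mean Pearson R across folds
#' @export
setMethod("meanR", "DecodeResult", function(x) x@meanR)

#' @describeIn PseudoPopulation-class stage design tensor
#' @param stage "early" or "late"
#' @export
setMethod("stageTensor", "PseudoPopulation", function(x, stage) {
  stage <- match.arg(stage, c("early", "late"))
  if (stage == "early") x@early else x@late
})

#' Coerce a trial table to a data.frame
#' @param x a [TrialTable-class]
#' @param ... ignored
#' @return data.frame with trial_id, onset, offset, duration, rewarded
#' @export
setMethod("as.data.frame", "TrialTable", function(x, ...) x@trials)

## show methods --------------------------------------------------------------

setMethod("show", "TrialTable", function(object) {
  n <- nrow(object@trials)
  cat(sprintf("TrialTable with %d trial%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    d <- object@trials$duration
    cat(sprintf("  durations: %.3f-%.3f s (mean %.3f)\n",
                min(d), max(d), mean(d)))
    cat(sprintf("  rewarded: %d (%.1f%%)\n", sum(object@trials$rewarded),
                100 * mean(object@trials$rewarded)))
  }
  invisible(NULL)
})

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet with %d unit%s\n", nrow(object@units),
              if (nrow(object@units) == 1) "" else "s"))
  if (nrow(object@units) > 0) {
    tab <- table(object@units$region)
    cat("  per region:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
    cat(sprintf("  animals: %s\n",
                paste(unique(object@units$animal), collapse = ", ")))
    cat(sprintf("  total spikes: %d\n", sum(lengths(object@spikes))))
  }
  invisible(NULL)
})

setMethod("show", "DoubleGaussParams", function(object) {
  cat(sprintf(paste0("DoubleGaussParams: gamma=%.3f  mu1=%.3f s  ",
                     "sigma1=%.3f s  mu2=%.3f s  sigma2=%.3f s\n"),
              object@gamma, object@mu1, object@sigma1, object@mu2,
              object@sigma2))
  invisible(NULL)
})

setMethod("show", "RateTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("RateTensor: %d trials x %d units x %d bins (%.0f ms bins, %s-aligned)\n",
              d[1], d[2], d[3], 1000 * object@binWidth, object@alignment))
  invisible(NULL)
})

setMethod("show", "PseudoPopulation", function(object) {
  d <- dim(object@early)
  cat(sprintf("PseudoPopulation: %d pseudo-trials/stage x %d units x %d bins (N=%d matched trials)\n",
              d[1], d[2], d[3], object@nMatched))
  invisible(NULL)
})

setMethod("show", "DecodeResult", function(object) {
  cat(sprintf("DecodeResult: mean R = %.3f (SD %.3f), 95%% CI [%.3f, %.3f]\n",
              object@meanR, object@sdR, object@ciMean[1], object@ciMean[2]))
  cat(sprintf("  %d folds, %d pseudo-trials, %d units, %d classes\n",
              object@nFolds, object@nTrials, object@nUnits,
              nrow(object@confusion)))
  invisible(NULL)
})

setMethod("show", "JackknifeResult", function(object) {
  cat(sprintf("JackknifeResult: corrected t(%d) = %.3f, p = %.4g (raw t = %.3f)\n",
              as.integer(object@df), object@correctedT, object@p, object@rawT))
  invisible(NULL)
})
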