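#' @include AllClasses.R constructors.R lda.R stats.R utils.R
NULL

#' Assemble a cross-animal pseudo-population
#'
#' Pools units across animals into a single "average animal". With N the
#' smallest per-animal reinforced-trial count, every animal contributes its
#' first floor(N/2) reinforced trials to the early stage and its last
#' floor(N/2) to the late stage; pseudo-trial k concatenates the k-th
#' selected trial's unit rates across animals. Only the decoded bins
#' (`dropFirst`/`dropLast` head/tail bins removed) enter the design tensors.
#'
#' @param rateTensors named list (one per animal) of [RateTensor-class]
#'   built from that animal's reinforced trials over the truncated window.
#' @param config a [DecoderConfig-class]
#' @return a [PseudoPopulation-class]
#' @export
buildPseudoPopulation <- function(rateTensors, config = DecoderConfig()) {
  if (length(rateTensors) < 1) .stopf("need at least one animal")
  if (is.null(names(rateTensors)))
    names(rateTensors) <- paste0("animal", seq_along(rateTensors))
  counts <- vapply(rateTensors, nTrials, integer(1))
  few <- which(counts < 2)
  if (length(few) > 0)
    .stopf("animal '%s' has only %d reinforced trial(s); need at least 2",
           names(rateTensors)[few[1]], counts[few[1]])
  N <- min(counts)
  half <- floor(N / 2)
  nbins <- dim(rateTensors[[1]]@values)[3]
  binIdx <- seq(config@dropFirst + 1, nbins - config@dropLast)
  if (length(binIdx) != config@nClasses)
    .stopf("decoded bin count %d does not match nClasses = %d",
           length(binIdx), config@nClasses)
  early <- late <- NULL
  units <- NULL
  for (a in names(rateTensors)) {
    rt <- rateTensors[[a]]
    na <- nTrials(rt)
    e <- rt@values[seq_len(half), , binIdx, drop = FALSE]
    l <- rt@values[seq(na - half + 1, na), , binIdx, drop = FALSE]
    ua <- rt@units
    ua$animal <- a
    units <- if (is.null(units)) ua else rbind(units, ua)
    if (is.null(early)) { early <- e; late <- l }
    else {
      ne <- dim(early)
      grown <- array(0, dim = c(ne[1], ne[2] + dim(e)[2], ne[3]))
      grown[, seq_len(ne[2]), ] <- early
      grown[, ne[2] + seq_len(dim(e)[2]), ] <- e
      early <- grown
      grown[, seq_len(ne[2]), ] <- late
      grown[, ne[2] + seq_len(dim(l)[2]), ] <- l
      late <- grown
    }
  }
  centers <- (rateTensors[[1]]@binEdges[-1] +
                rateTensors[[1]]@binEdges[-(nbins + 1)]) / 2
  new("PseudoPopulation", early = early, late = late, units = units,
      nMatched = as.integer(N), binTimes = centers[binIdx])
}

#' Robust feature normalisation
#'
#' Centers and scales each feature (column) by the median and interquartile
#' range computed on the training set only, applying the same transform to
#' the test set. Features with zero IQR are centred but not scaled.
#'
#' @param train,test numeric matrices with matching columns.
#' @return list with normalised `train` and `test` matrices.
#' @export
robustNormalize <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) == 0) .stopf("training set is empty")
  if (ncol(train) != ncol(test)) .stopf("train/test column mismatch")
  med <- apply(train, 2, stats::median)
  q <- apply(train, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- q[2, ] - q[1, ]
  iqr[iqr == 0] <- 1
  list(train = sweep(sweep(train, 2, med), 2, iqr, "/"),
       test = sweep(sweep(test, 2, med), 2, iqr, "/"))
}

#' Pearson correlation between actual and predicted time bins
#'
#' Sample Pearson correlation between the true bin indices and the decoded
#' (highest-probability) bin indices. If either vector is constant the
#' correlation is 0 by convention.
#'
#' @param actual,predicted equal-length numeric vectors (length >= 2).
#' @return correlation in \[-1, 1\].
#' @export
pearsonR <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    .stopf("actual and predicted lengths differ")
  if (length(actual) < 2) .stopf("need at least 2 values")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) return(0)
  stats::cor(actual, predicted)
}

#' Cross-validated time-bin decoding
#'
#' Trial-grouped cross-validation of the shrinkage discriminant: in each of
#' `nFolds` random folds, `ceiling(trainFraction * n)` pseudo-trials are
#' drawn without replacement as the training set and the rest are tested,
#' so the K bins of one trial are always together in either set. Each trial
#' contributes exactly one sample per class (its population rate vector in
#' each decoded bin). Features are normalised per unit by training-set
#' median/IQR, the discriminant is fit with Ledoit-Wolf shrinkage, and test
#' bins receive per-class probabilities. Per fold, the Pearson correlation
#' between true and highest-probability bin (ties broken toward the lowest
#' bin) is recorded; per-class probability profiles are averaged across
#' folds into the confusion matrix.
#'
#' @param tensor numeric array, pseudo-trials x units x decoded bins (K),
#'   with at least 5 pseudo-trials; or the value of [stageTensor()].
#' @param config a [DecoderConfig-class]
#' @param shrinkage passed to [fitDiscriminant()] ("auto" by default).
#' @return a [DecodeResult-class]
#' @export
crossvalidate <- function(tensor, config = DecoderConfig(),
                          shrinkage = "auto") {
  stopifnot(length(dim(tensor)) == 3)
  n <- dim(tensor)[1]; p <- dim(tensor)[2]; K <- dim(tensor)[3]
  if (n < 5) .stopf("need at least 5 pseudo-trials; got %d", n)
  if (p < 1) .stopf("empty population: no units to decode from")
  nTrain <- ceiling(config@trainFraction * n)
  if (n - nTrain < 2) {
    nTrain <- n - 2L
    .warnf("train fraction leaves < 2 test trials; using %d training trials",
           nTrain)
  }
  ## rows: bin fastest within trial -> sample (trial i, bin k) = (i-1)*K + k
  Xall <- matrix(aperm(tensor, c(3, 1, 2)), nrow = n * K, ncol = p)
  yall <- rep(seq_len(K), times = n)
  conf <- matrix(0, K, K)
  foldRs <- numeric(config@nFolds)
  withr::with_seed(config@seed, {
    for (f in seq_len(config@nFolds)) {
      trainTrials <- sample.int(n, nTrain)
      testTrials <- setdiff(seq_len(n), trainTrials)
      trRows <- as.vector(outer(seq_len(K), (trainTrials - 1) * K, "+"))
      teRows <- as.vector(outer(seq_len(K), (testTrials - 1) * K, "+"))
      nrm <- robustNormalize(Xall[trRows, , drop = FALSE],
                             Xall[teRows, , drop = FALSE])
      model <- fitDiscriminant(nrm$train, yall[trRows],
                               classes = seq_len(K), shrinkage = shrinkage)
      probs <- predictDiscriminant(model, nrm$test)
      yTest <- yall[teRows]
      predicted <- max.col(probs, ties.method = "first")
      foldRs[f] <- pearsonR(yTest, predicted)
      for (k in seq_len(K))
        conf[k, ] <- conf[k, ] + colMeans(probs[yTest == k, , drop = FALSE])
    }
  })
  conf <- conf / config@nFolds
  fs <- foldSummary(foldRs, seed = .deriveSeed(config@seed, 7L))
  new("DecodeResult", confusion = conf, foldR = foldRs, meanR = fs$mean,
      sdR = fs$sd, ciMean = fs$ci, nFolds = config@nFolds,
      nTrials = as.integer(n), nUnits = as.integer(p))
}

#' Decode one stage of a pseudo-population
#'
#' Convenience wrapper: [crossvalidate()] applied to the early or late
#' design tensor of a [PseudoPopulation-class].
#'
#' @param pop a [PseudoPopulation-class]
#' @param stage "early" or "late".
#' @param config a [DecoderConfig-class]
#' @param shrinkage passed to [fitDiscriminant()].
#' @return a [DecodeResult-class]
#' @export
decodeStage <- function(pop, stage, config = DecoderConfig(),
                        shrinkage = "auto") {
  crossvalidate(stageTensor(pop, stage), config, shrinkage = shrinkage)
}
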