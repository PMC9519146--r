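# Independent reference implementations used as oracles. These deliberately
# take different computational paths from the package code.

# Shared-covariance Gaussian classifier, shrinkage 0: per-test-sample loop
# over classes using the full quadratic log-density (the package uses the
# linear discriminant scores; the two posteriors agree analytically).
naiveSharedCovProbs <- function(Xtr, ytr, Xte, classes = sort(unique(ytr))) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  K <- length(classes)
  p <- ncol(Xtr)
  mus <- lapply(classes, function(k) colMeans(Xtr[ytr == k, , drop = FALSE]))
  centred <- Xtr
  for (i in seq_len(K))
    centred[ytr == classes[i], ] <-
      sweep(Xtr[ytr == classes[i], , drop = FALSE], 2, mus[[i]])
  Sigma <- crossprod(centred) / nrow(Xtr)
  Sinv <- solve(Sigma)
  logPrior <- log(vapply(classes, function(k) mean(ytr == k), numeric(1)))
  probs <- matrix(NA_real_, nrow(Xte), K)
  for (i in seq_len(nrow(Xte))) {
    ll <- vapply(seq_len(K), function(k) {
      d <- Xte[i, ] - mus[[k]]
      -0.5 * drop(t(d) %*% Sinv %*% d) + logPrior[k]
    }, numeric(1))
    e <- exp(ll - max(ll))
    probs[i, ] <- e / sum(e)
  }
  probs
}

# Textbook leave-one-out jackknife comparison, written independently.
bruteJackknife <- function(statFn, animals, condA, condB, seed) {
  N <- length(animals)
  d <- numeric(N)
  for (i in 1:N) {
    keep <- animals[setdiff(1:N, i)]
    d[i] <- statFn(keep, condA, seed) - statFn(keep, condB, seed)
  }
  se <- sqrt(sum((d - mean(d))^2) / (N - 1)) / sqrt(N)
  tRaw <- mean(d) / se
  tCorr <- tRaw / (N - 1)
  list(diffs = d, rawT = tRaw, correctedT = tCorr,
       p = 2 * pt(-abs(tCorr), df = N - 1))
}

# Direct scalar evaluation of the unnormalised two-Gaussian mixture.
directMixture <- function(t, gamma, mu1, s1, mu2, s2) {
  (1 - gamma) * exp(-(t - mu1)^2 / (2 * s1^2)) +
    gamma * exp(-(t - mu2)^2 / (2 * s2^2))
}
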