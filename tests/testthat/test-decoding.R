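test_that("robust normalisation uses training medians and IQRs", {
  train <- cbind(c(1, 2, 3, 4, 5))
  test <- cbind(c(3, 5))
  nrm <- robustNormalize(train, test)
  # median 3, IQR 2: value 5 maps to 1.0
  expect_equal(nrm$test[, 1], c(0, 1))
  expect_equal(nrm$train[, 1], c(-1, -0.5, 0, 0.5, 1))
  # already median-0/IQR-1 features are unchanged
  again <- robustNormalize(nrm$train, nrm$test)
  expect_equal(again$train, nrm$train)
  # constant features are centred only
  cst <- robustNormalize(cbind(rep(7, 4)), cbind(9))
  expect_equal(cst$test[, 1], 2)
})

test_that("pearsonR follows the stated conventions", {
  expect_equal(pearsonR(1:10, 1:10), 1)
  expect_equal(pearsonR(1:10, 10:1), -1)
  expect_equal(pearsonR(1:10, rep(3, 10)), 0)
  expect_error(pearsonR(1, 1), "at least 2")
  expect_error(pearsonR(1:3, 1:4), "differ")
})

test_that("the discriminant separates distant clouds and reports missing classes", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 50), 20))
  y <- rep(1:2, each = 20)
  m <- fitDiscriminant(X, y)
  pr <- predictDiscriminant(m, X)
  expect_equal(max.col(pr), y)
  expect_error(fitDiscriminant(X, y, classes = 1:3), "class 3 absent")
  # perfect collinearity: shrinkage keeps the fit well-posed
  Xd <- cbind(X, X)
  expect_no_error(fitDiscriminant(Xd, y, shrinkage = "auto"))
})

test_that("label permutation drives accuracy to chance", {
  set.seed(8)
  K <- 4
  X <- matrix(rnorm(400 * 3), 400)
  y <- sample(rep(1:K, 100))
  m <- fitDiscriminant(X, y)
  acc <- mean(max.col(predictDiscriminant(m, X)) == y)
  expect_lt(abs(acc - 1 / K), 0.12)
})

test_that("fold predictions match the shrinkage-0 brute-force discriminant", {
  # small instances: up to 6 trials x 2 units x 3 bins
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:6, 1)
    tensor <- array(rexp(n * 2 * 3, rate = 0.2), dim = c(n, 2, 3))
    # reproduce the fold loop with the naive full-Gaussian oracle
    cfg <- DecoderConfig(nFolds = 20, nClasses = 3, dropFirst = 0,
                         dropLast = 0, seed = 50 + seed)
    got <- suppressWarnings(crossvalidate(tensor, cfg, shrinkage = 0))
    K <- 3
    Xall <- matrix(aperm(tensor, c(3, 1, 2)), nrow = n * K, ncol = 2)
    yall <- rep(1:K, times = n)
    nTrain <- n - 2  # ceiling(0.8 n) leaves < 2 test trials at this n
    confRef <- matrix(0, K, K)
    foldRef <- numeric(cfg@nFolds)
    withr::with_seed(cfg@seed, {
      for (f in seq_len(cfg@nFolds)) {
        tr <- sample.int(n, nTrain)
        te <- setdiff(seq_len(n), tr)
        trRows <- as.vector(outer(1:K, (tr - 1) * K, "+"))
        teRows <- as.vector(outer(1:K, (te - 1) * K, "+"))
        med <- apply(Xall[trRows, , drop = FALSE], 2, median)
        iqr <- apply(Xall[trRows, , drop = FALSE], 2, IQR)
        iqr[iqr == 0] <- 1
        scale <- function(M) sweep(sweep(M, 2, med), 2, iqr, "/")
        probs <- naiveSharedCovProbs(scale(Xall[trRows, , drop = FALSE]),
                                     yall[trRows],
                                     scale(Xall[teRows, , drop = FALSE]))
        yTest <- yall[teRows]
        pred <- max.col(probs, ties.method = "first")
        foldRef[f] <- if (sd(pred) == 0) 0 else cor(yTest, pred)
        for (k in 1:K)
          confRef[k, ] <- confRef[k, ] +
            colMeans(probs[yTest == k, , drop = FALSE])
      }
    })
    expect_equal(got@foldR, foldRef, tolerance = 1e-10)
    expect_equal(unname(confusionMatrix(got)), confRef / cfg@nFolds,
                 tolerance = 1e-10)
  }
})

test_that("deterministic signatures decode perfectly; permuted labels at chance", {
  # disjoint per-bin population patterns: identity confusion and R = 1
  K <- 5; n <- 12
  base <- diag(K) * 10
  tensor <- array(0, dim = c(n, K, K))
  for (i in 1:n) tensor[i, , ] <- base + 0.01 * i
  cfg <- DecoderConfig(nFolds = 40, nClasses = K, dropFirst = 0,
                       dropLast = 0, seed = 3)
  res <- crossvalidate(tensor, cfg)
  expect_equal(meanR(res), 1)
  expect_equal(which(confusionMatrix(res) ==
                       apply(confusionMatrix(res), 1, max)),
               which(diag(K) == 1))
  # permuting bin labels within each trial removes the signal
  set.seed(99)
  perm <- tensor
  for (i in 1:n) perm[i, , ] <- tensor[i, , sample(K)]
  resP <- crossvalidate(perm, DecoderConfig(nFolds = 200, nClasses = K,
                                            dropFirst = 0, dropLast = 0,
                                            seed = 4))
  expect_lt(abs(meanR(resP)), 0.25)
})

test_that("confusion rows are probability vectors and folds are seeded", {
  set.seed(2)
  tensor <- array(rnorm(10 * 4 * 6, 10), dim = c(10, 4, 6))
  cfg <- DecoderConfig(nFolds = 30, nClasses = 6, dropFirst = 0,
                       dropLast = 0, seed = 12)
  r1 <- crossvalidate(tensor, cfg)
  r2 <- crossvalidate(tensor, cfg)
  expect_equal(rowSums(confusionMatrix(r1)), rep(1, 6), tolerance = 1e-9)
  expect_identical(foldR(r1), foldR(r2))
  expect_identical(r1@ciMean, r2@ciMean)
})

test_that("mean R is invariant to unit ordering (within Monte-Carlo error)", {
  tt <- makeTrials(40)
  cfg <- populationGenConfig(tilingTimeCells(8, baseline = 2, peak = 15),
                             counts = rep(1, 8), animal = "r1", seed = 61)
  rt <- animalRateTensor(tt, cfg)
  dcfg <- DecoderConfig(nFolds = 150, seed = 5)
  bins <- 3:12
  a <- crossvalidate(rt@values[, , bins], dcfg)
  b <- crossvalidate(rt@values[, 8:1, bins], dcfg)
  expect_lt(abs(meanR(a) - meanR(b)), 0.05)
})

test_that("pseudo-populations match trial counts across animals", {
  mkRt <- function(n, units, seed) {
    set.seed(seed)
    new("RateTensor", values = array(rexp(n * units * 15), c(n, units, 15)),
        binEdges = seq(0, 1.5, 0.1), binWidth = 0.1, kernelSigma = 0.1,
        alignment = "onset", trialIds = seq_len(n),
        units = data.frame(unit_id = seq_len(units), region = "mPFC",
                           animal = "x"))
  }
  pop <- buildPseudoPopulation(list(a = mkRt(30, 4, 1), b = mkRt(45, 5, 2),
                                    c = mkRt(60, 3, 3)))
  expect_equal(pop@nMatched, 30L)
  expect_equal(dim(stageTensor(pop, "early")), c(15, 12, 10))
  # unit concatenation: 4 + 5 units -> 9 feature dimensions
  p2 <- buildPseudoPopulation(list(a = mkRt(30, 4, 1), b = mkRt(40, 5, 2)))
  expect_equal(nUnits(p2), 9L)
  # late trials come from each animal's session end
  rtB <- mkRt(40, 5, 2)
  expect_equal(stageTensor(p2, "late")[15, 5:9, 1],
               unname(rtB@values[40, , 3]))
  # single animal: the population is that animal's own halves
  p1 <- buildPseudoPopulation(list(a = mkRt(30, 4, 1)))
  rtA <- mkRt(30, 4, 1)
  expect_equal(stageTensor(p1, "early")[1, , 1], unname(rtA@values[1, , 3]))
  expect_error(buildPseudoPopulation(list(a = mkRt(30, 4, 1),
                                          b = mkRt(1, 2, 2))), "animal 'b'")
})
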