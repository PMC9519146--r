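test_that("the mixture density normalises discretely and matches direct evaluation", {
  g <- doubleGaussianDensity(DoubleGaussParams(0.5, 0.2, 0.1, 1, 0.5))
  expect_equal(sum(g@p) * g@dt, 1, tolerance = 1e-13)
  expect_equal(length(g@t), 61L)
  # scalar oracle: direct evaluation of the unnormalised mixture at t = 0.2
  expect_equal(g@f[g@t == 0.2],
               0.5 * (1 + exp(-(0.2 - 1)^2 / (2 * 0.25))),
               tolerance = 1e-12)
  expect_equal(g@f[g@t == 0.2],
               directMixture(0.2, 0.5, 0.2, 0.1, 1, 0.5), tolerance = 1e-15)
})

test_that("a collapsed mixture is a discretely normalised single Gaussian", {
  g <- doubleGaussianDensity(DoubleGaussParams(0, 1.0, 0.2, 1.0, 0.2))
  expect_equal(g@t[which.max(g@p)], 1.0)
  expect_equal(sum(g@p) * g@dt, 1, tolerance = 1e-13)
})

test_that("the density is invariant under swapping the two modes", {
  a <- doubleGaussianDensity(DoubleGaussParams(0.3, 0.4, 0.15, 1.6, 0.5))
  # swapped: modes exchanged and gamma -> 1 - gamma; same f up to relabeling
  fSwapped <- directMixture(a@t, 1 - 0.3, 1.6, 0.5, 0.4, 0.15)
  expect_equal(a@f, fSwapped, tolerance = 1e-14)
})

test_that("degenerate densities raise an error", {
  # both modes centred far outside the 0-6 s grid
  expect_error(doubleGaussianDensity(DoubleGaussParams(0.5, 50, 0.01, 60, 0.01)),
               "degenerate")
})

test_that("parameter recovery from sampled durations is accurate", {
  truth <- DoubleGaussParams(0.6, 0.3, 0.1, 1.7, 0.4)
  d <- withr::with_seed(42, sampleDurations(2000, truth))
  fit <- fitDoubleGaussian(d)
  expect_lt(abs(fit$params@gamma - 0.6), 0.05)
  expect_lt(abs(fit$params@mu1 - 0.3), 0.05)
  expect_lt(abs(fit$params@sigma1 - 0.1), 0.05)
  expect_lt(abs(fit$params@mu2 - 1.7), 0.05)
  expect_lt(abs(fit$params@sigma2 - 0.4), 0.05)
  expect_true(fit$converged)
})

test_that("a unimodal sample is fit with gamma near 1 after canonicalisation", {
  d <- withr::with_seed(7, rnorm(3000, 1.5, 0.3))
  fit <- fitDoubleGaussian(d)
  expect_gte(fit$params@gamma, 0.9)
  expect_lt(abs(fit$params@mu2 - 1.5), 0.05)
  expect_lte(fit$params@mu1, fit$params@mu2)
})

test_that("refitting the fitted density recovers the same parameters", {
  truth <- DoubleGaussParams(0.55, 0.35, 0.12, 1.6, 0.45)
  d1 <- withr::with_seed(11, sampleDurations(10000, truth))
  p1 <- fitDoubleGaussian(d1)$params
  d2 <- withr::with_seed(12, sampleDurations(10000, p1))
  p2 <- fitDoubleGaussian(d2)$params
  expect_lt(abs(p2@gamma - p1@gamma), 0.05)
  expect_lt(abs(p2@mu1 - p1@mu1), 0.05)
  expect_lt(abs(p2@mu2 - p1@mu2), 0.05)
})

test_that("mode order is canonical on every fit", {
  # start values put mu1 on the long mode: fit must still return mu1 <= mu2
  d <- withr::with_seed(5, sampleDurations(2000,
                        DoubleGaussParams(0.4, 0.3, 0.1, 1.8, 0.3)))
  fit <- fitDoubleGaussian(d, start = list(gamma = 0.5, mu1 = 1.8,
                                           sigma1 = 0.3, mu2 = 0.3,
                                           sigma2 = 1))
  expect_lte(fit$params@mu1, fit$params@mu2)
})

test_that("too few samples and durations beyond the grid are handled", {
  expect_error(fitDoubleGaussian(rep(1, 10)), "at least 30")
  d <- c(withr::with_seed(3, sampleDurations(500,
         DoubleGaussParams(0.6, 0.3, 0.1, 1.7, 0.4))), 7.5)
  expect_message(fitDoubleGaussian(d), "> 6 s")
})

test_that("sessions split into early and late halves", {
  tt <- makeTrials(100)
  sp <- splitEarlyLate(tt)
  expect_equal(as.data.frame(sp$early)$trial_id, 1:50)
  expect_equal(as.data.frame(sp$late)$trial_id, 51:100)
  # matched count: first and last n/2
  sp30 <- splitEarlyLate(makeTrials(60), n = 30)
  expect_equal(as.data.frame(sp30$early)$trial_id, 1:15)
  expect_equal(as.data.frame(sp30$late)$trial_id, 46:60)
  # odd totals: extra trial to early
  sp5 <- splitEarlyLate(makeTrials(5))
  expect_equal(nTrials(sp5$early), 3L)
  expect_equal(nTrials(sp5$late), 2L)
  expect_error(splitEarlyLate(makeTrials(2), n = 10), "exceeds")
  expect_error(splitEarlyLate(TrialTable(1L, 0.5, 1.5, TRUE)), "at least 2")
})

test_that("behaviour summaries aggregate per animal and group", {
  t1 <- trialsFromDurations(c(1, 1, 1, 2, 2, 2))
  s <- summarizeBehavior(list(a = t1, b = t1))
  expect_equal(s$perAnimal$mean_early, c(1, 1))
  expect_equal(s$perAnimal$mean_late, c(2, 2))
  expect_equal(s$group$mean, c(1, 2))
  expect_equal(s$group$sem, c(0, 0))  # identical animals
})

test_that("simulated learning increases late durations for every animal", {
  sessions <- lapply(1:3, function(i)
    simulateBehavior(behaviorGenConfig(
      nTrials = 500,
      startParams = DoubleGaussParams(0.1, 0.35, 0.15, 1.7, 0.5),
      endParams = DoubleGaussParams(0.9, 0.35, 0.15, 1.7, 0.5),
      seed = 100 + i)))
  names(sessions) <- paste0("r", 1:3)
  s <- summarizeBehavior(sessions)
  expect_true(all(s$perAnimal$mean_late > s$perAnimal$mean_early))
})
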