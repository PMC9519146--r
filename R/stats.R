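#' @include AllClasses.R utils.R
NULL

#' Jackknife leave-one-animal-out comparison
#'
#' Computes a statistic's between-condition difference N times, omitting one
#' animal per run, then tests the N leave-one-out differences with a
#' one-sample t. Because the leave-one-out runs are strongly dependent, the
#' raw t is divided by N - 1 (the jackknife correction) before computing a
#' two-sided p-value on N - 1 degrees of freedom.
#'
#' @param statFn function `(animals, condition, seed)` returning a scalar
#'   statistic computed on a subset of animals under one condition;
#'   deterministic given the seed.
#' @param animals vector of animal identifiers (N >= 3).
#' @param condA,condB the two condition labels passed to `statFn`.
#' @param seed seed forwarded to `statFn` so stochastic statistics (such as
#'   the cross-validated decoder) are reproducible across runs.
#' @param df degrees of freedom for the p-value (default N - 1).
#' @return a [JackknifeResult-class]
#' @export
jackknifeCompare <- function(statFn, animals, condA, condB, seed = 1,
                             df = length(animals) - 1) {
  N <- length(animals)
  if (N < 3) .stopf("need at least 3 animals; got %d", N)
  diffs <- vapply(seq_len(N), function(i) {
    rest <- animals[-i]
    statFn(rest, condA, seed) - statFn(rest, condB, seed)
  }, numeric(1))
  s <- stats::sd(diffs)
  if (s == 0)
    .stopf("zero variance across jackknife runs (constant difference %g); t undefined",
           diffs[1])
  rawT <- mean(diffs) / (s / sqrt(N))
  corrT <- rawT / (N - 1)
  p <- 2 * stats::pt(-abs(corrT), df = df)
  new("JackknifeResult", values = diffs, rawT = rawT, correctedT = corrT,
      df = as.numeric(df), p = p)
}

#' Cohen's d effect size
#'
#' Paired: mean of the differences divided by their SD. Unpaired: mean
#' difference divided by the pooled SD.
#'
#' @param a,b numeric samples (equal length when paired).
#' @param paired logical.
#' @return Cohen's d.
#' @export
cohensD <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) .stopf("need at least 2 values per sample")
  if (paired) {
    if (length(a) != length(b)) .stopf("paired samples must have equal sizes")
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) .stopf("zero variance of the paired differences; d undefined")
    mean(d) / s
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    if (sp2 == 0) .stopf("zero pooled variance; d undefined")
    (mean(a) - mean(b)) / sqrt(sp2)
  }
}

#' Summarise a per-fold statistic distribution
#'
#' Mean, SD and a 2.5-97.5 percentile interval of bootstrap means over the
#' fold distribution (seeded, reproducible).
#'
#' @param values per-fold statistic values (length >= 2).
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `ci` (length-2 numeric).
#' @export
foldSummary <- function(values, nBoot = 10000, seed = 1) {
  if (length(values) < 2) .stopf("need at least 2 values")
  n <- length(values)
  withr::with_seed(seed, {
    bootMeans <- vapply(seq_len(nBoot), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  list(mean = mean(values), sd = stats::sd(values),
       ci = unname(stats::quantile(bootMeans, c(0.025, 0.975))))
}

#' Paired t-test
#'
#' Classical two-sided paired t-test (delegates to [stats::t.test()]).
#'
#' @param a,b equal-length numeric samples (n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) .stopf("paired samples must have equal sizes")
  if (length(a) < 2) .stopf("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (isTRUE(all.equal(mean(d), 0)))
      return(list(t = 0, df = length(a) - 1, p = 1))
    .stopf("zero variance of the paired differences; t undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
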