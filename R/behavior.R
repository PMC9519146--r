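#' @include AllClasses.R constructors.R utils.R
NULL

## Bimodal response-duration model. Hold durations in the task fall into a
## premature mode (short pokes released before the animal times out) and a
## temporally controlled mode near or beyond the 1.5 s criterion. The model
## is an unnormalised two-Gaussian mixture
##   f(t) = (1 - gamma) exp(-(t - mu1)^2 / (2 sigma1^2))
##        +      gamma  exp(-(t - mu2)^2 / (2 sigma2^2))
## normalised discretely on the grid t_i = i * 0.1 s, i = 0..60:
##   p(t_i) = f(t_i) / xi,  xi = dt * sum_i f(t_i).

.DGRID_DT <- 0.1
.DGRID_T <- seq(0, 6, by = 0.1)

.dgaussF <- function(t, gamma, mu1, sigma1, mu2, sigma2) {
  (1 - gamma) * exp(-(t - mu1)^2 / (2 * sigma1^2)) +
    gamma * exp(-(t - mu2)^2 / (2 * sigma2^2))
}

#' Evaluate the double-Gaussian density on its grid
#'
#' Evaluates the unnormalised mixture `f` on the fixed grid
#' `ti = i * 0.1 s, i = 0..60`, computes the discrete normalisation term
#' `xi = dt * sum(f)` and returns the normalised density `p = f / xi`, which
#' satisfies `sum(p) * dt == 1`.
#'
#' @param params a [DoubleGaussParams-class]
#' @return a [DensityGrid-class]
#' @examples
#' g <- doubleGaussianDensity(DoubleGaussParams(0.5, 0.2, 0.1, 1, 0.5))
#' sum(g@p) * g@dt  # 1
#' @export
doubleGaussianDensity <- function(params) {
  stopifnot(is(params, "DoubleGaussParams"))
  validObject(params)
  f <- .dgaussF(.DGRID_T, params@gamma, params@mu1, params@sigma1,
                params@mu2, params@sigma2)
  xi <- .DGRID_DT * sum(f)
  if (xi == 0)
    .stopf("degenerate density: both modes are numerically zero on [0, 6] s")
  new("DensityGrid", t = .DGRID_T, f = f, xi = xi, p = f / xi, dt = .DGRID_DT)
}

#' Draw response durations from the double-Gaussian model
#'
#' Samples from the continuous mixture corresponding to the unnormalised
#' amplitudes: the timed mode is chosen with probability
#' `gamma * sigma2 / ((1 - gamma) * sigma1 + gamma * sigma2)` (the component
#' masses of `f`), and draws below `minDuration` are rejected and redrawn
#' (pokes shorter than 50 ms are not registered by the task hardware).
#'
#' @param n number of durations.
#' @param params a [DoubleGaussParams-class]
#' @param minDuration rejection floor in seconds (default 0.05).
#' @return numeric vector of durations (seconds). Uses the current RNG
#'   state; seed externally for reproducibility.
#' @export
sampleDurations <- function(n, params, minDuration = 0.05) {
  stopifnot(is(params, "DoubleGaussParams"))
  validObject(params)
  m1 <- (1 - params@gamma) * params@sigma1
  m2 <- params@gamma * params@sigma2
  if (m1 + m2 <= 0) .stopf("degenerate mixture: both component masses are zero")
  w2 <- m2 / (m1 + m2)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    pick2 <- stats::runif(length(todo)) < w2
    mu <- ifelse(pick2, params@mu2, params@mu1)
    sd <- ifelse(pick2, params@sigma2, params@sigma1)
    x <- stats::rnorm(length(todo), mu, sd)
    ok <- x >= minDuration
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Split a session into early and late trials
#'
#' Without `n`, the session is halved: the first half is early and the
#' second half late (odd totals assign the middle trial to early). With `n`,
#' the first `n/2` trials are early and the last `n/2` late, mirroring the
#' trial-count matching used when pooling animals.
#'
#' @param trials a [TrialTable-class] with at least 2 trials.
#' @param n optional matched trial count (`n <= nTrials(trials)`).
#' @return list with elements `early` and `late` ([TrialTable-class]).
#' @export
splitEarlyLate <- function(trials, n = NULL) {
  stopifnot(is(trials, "TrialTable"))
  total <- nrow(trials@trials)
  if (total < 2) .stopf("need at least 2 trials to split; got %d", total)
  if (is.null(n)) {
    nEarly <- ceiling(total / 2)
    early <- trials@trials[seq_len(nEarly), , drop = FALSE]
    late <- trials@trials[seq(nEarly + 1, total), , drop = FALSE]
  } else {
    if (n > total) .stopf("n = %d exceeds the trial count %d", n, total)
    if (n < 2) .stopf("n must be >= 2")
    half <- floor(n / 2)
    early <- trials@trials[seq_len(half), , drop = FALSE]
    late <- trials@trials[seq(total - half + 1, total), , drop = FALSE]
  }
  rownames(early) <- rownames(late) <- NULL
  list(early = new("TrialTable", trials = early),
       late = new("TrialTable", trials = late))
}

#' Fit the double-Gaussian model to response durations
#'
#' The durations are histogrammed on the density grid (bins of width 0.1 s
#' centred on the grid points, range 0-6 s, normalised to a density) and the
#' normalised model density `p(ti)` is fit to the histogram by bounded
#' Levenberg-Marquardt least squares. Optimisation starts from the
#' conventional initial values gamma = 0.5, mu1 = 0.2, sigma1 = 0.1,
#' mu2 = 1, sigma2 = 0.5, with bounds gamma in \[0, 1\] and sigma >= 0.01.
#' If the fitted modes come out reversed (mu1 > mu2) they are swapped and
#' gamma mapped to 1 - gamma, so the returned parameters always satisfy
#' mu1 <= mu2. Durations above 6 s lie outside the grid and are excluded
#' from the histogram (with a message).
#'
#' Because the gamma bound is an absorbing stationary point of the
#' Levenberg-Marquardt iteration (at gamma = 0 or 1 the silent mode's
#' parameters have zero gradient), the optimiser is additionally restarted
#' from a fixed set of alternative initial values and the solution with the
#' smallest residual norm is returned.
#'
#' @param durations numeric vector of response durations (seconds).
#' @param minSamples minimum number of durations required (default 30).
#' @param start optional named list or vector (gamma, mu1, sigma1, mu2,
#'   sigma2) overriding the default initial values; need not be in canonical
#'   mode order.
#' @return list with `params` ([DoubleGaussParams-class]), `residualNorm`
#'   (Euclidean norm of the density residuals), `n` (durations used) and
#'   `converged` (logical).
#' @export
fitDoubleGaussian <- function(durations, minSamples = 30, start = NULL) {
  durations <- durations[is.finite(durations)]
  if (length(durations) < minSamples)
    .stopf("need at least %d durations to fit; got %d", minSamples,
           length(durations))
  over <- durations > 6 + .DGRID_DT / 2
  if (any(over)) {
    message(sprintf("%d duration(s) > 6 s excluded from the fit histogram",
                    sum(over)))
    durations <- durations[!over]
  }
  breaks <- seq(-.DGRID_DT / 2, 6 + .DGRID_DT / 2, by = .DGRID_DT)
  counts <- graphics::hist(pmin(pmax(durations, 0), 6), breaks = breaks,
                           plot = FALSE)$counts
  dens <- counts / (length(durations) * .DGRID_DT)
  residFn <- function(par) {
    f <- .dgaussF(.DGRID_T, par[1], par[2], par[3], par[4], par[5])
    xi <- .DGRID_DT * sum(f)
    if (xi == 0) return(dens)  # degenerate iterate: full residual
    dens - f / xi
  }
  starts <- list(c(0.5, 0.2, 0.1, 1, 0.5),       # conventional initial values
                 c(0.9, 0.3, 0.1, 1.8, 0.4),     # timed-mode dominant
                 c(0.1, 0.3, 0.1, 1.2, 0.5),     # premature-mode dominant
                 c(0.5, 0.5, 0.2, 2.0, 0.5))     # wide/late modes
  if (!is.null(start)) {
    start <- as.list(start)
    starts <- c(list(unlist(start[c("gamma", "mu1", "sigma1", "mu2",
                                    "sigma2")], use.names = FALSE)),
                starts)
  }
  fits <- list()
  for (s0 in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = residFn,
                         lower = c(0, -Inf, 0.01, -Inf, 0.01),
                         upper = c(1, Inf, Inf, Inf, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(out) || !out$info %in% 1:4) next
    fits[[length(fits) + 1]] <- list(par = out$par,
                                     rnorm = sqrt(sum(out$fvec^2)))
  }
  if (length(fits) == 0)
    .stopf("double-Gaussian fit did not converge from any initial value")
  ## near-degenerate data (e.g. unimodal, modes coinciding) leaves gamma
  ## unidentifiable and several starts tie: among solutions within 5% of the
  ## best residual norm, keep the earliest start (the conventional one)
  rnorms <- vapply(fits, `[[`, numeric(1), "rnorm")
  best <- fits[[which(rnorms <= 1.05 * min(rnorms))[1]]]
  est <- best$par
  gamma <- est[1]; mu1 <- est[2]; s1 <- est[3]; mu2 <- est[4]; s2 <- est[5]
  if (mu1 > mu2) {  # canonical mode order
    tmp <- c(mu1, s1); mu1 <- mu2; s1 <- s2; mu2 <- tmp[1]; s2 <- tmp[2]
    gamma <- 1 - gamma
  }
  params <- DoubleGaussParams(gamma, mu1, s1, mu2, s2)
  list(params = params,
       residualNorm = best$rnorm,
       n = length(durations),
       converged = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise early/late behaviour across animals
#'
#' Per-animal mean early and late response durations plus across-animal
#' group mean and SEM for each stage.
#'
#' @param sessions named list of [TrialTable-class], one per animal.
#' @param n optional matched trial count passed to [splitEarlyLate()].
#' @return list with `perAnimal` (data.frame: animal, n_early, n_late,
#'   mean_early, mean_late) and `group` (data.frame: stage, mean, sem, n).
#' @export
summarizeBehavior <- function(sessions, n = NULL) {
  if (length(sessions) < 1) .stopf("need at least one animal")
  if (is.null(names(sessions)))
    names(sessions) <- paste0("animal", seq_along(sessions))
  per <- do.call(rbind, lapply(names(sessions), function(a) {
    sp <- splitEarlyLate(sessions[[a]], n = n)
    ne <- nrow(sp$early@trials); nl <- nrow(sp$late@trials)
    if (ne == 0 || nl == 0) .stopf("empty stage window for animal '%s'", a)
    data.frame(animal = a, n_early = ne, n_late = nl,
               mean_early = mean(sp$early@trials$duration),
               mean_late = mean(sp$late@trials$duration),
               stringsAsFactors = FALSE)
  }))
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  group <- data.frame(
    stage = c("early", "late"),
    mean = c(mean(per$mean_early), mean(per$mean_late)),
    sem = c(sem(per$mean_early), sem(per$mean_late)),
    n = nrow(per))
  list(perAnimal = per, group = group)
}
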