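#' @include AllClasses.R constructors.R utils.R
NULL

#' Select reinforced trials for decoding
#'
#' Keeps trials whose hold duration meets the reinforcement criterion
#' (closed lower bound: a duration of exactly `criterion` is rewarded) and
#' is strictly below the upper cap, preserving trial order.
#'
#' @param trials a [TrialTable-class]
#' @param task a [TaskConfig-class] (criterion 1.5 s, cap 3.5 s by default).
#' @return a [TrialTable-class] (possibly empty, with a warning).
#' @export
selectReinforced <- function(trials, task = TaskConfig()) {
  stopifnot(is(trials, "TrialTable"))
  tr <- trials@trials
  keep <- tr$duration >= task@criterion & tr$duration < task@upperCap
  if (!any(keep))
    .warnf("no trials within [%.2f, %.2f) s; empty selection",
           task@criterion, task@upperCap)
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("TrialTable", trials = out)
}

#' Epoch spike trains around trials
#'
#' Cuts each unit's spike train to the per-trial analysis epoch
#' \[onset - preOnset, offset\] and re-references the times to the chosen
#' alignment event: with `"onset"` alignment times run from `-preOnset` to
#' the trial duration; with `"offset"` alignment all times are negative or
#' zero. If consecutive epochs overlap (inter-trial gap shorter than
#' `preOnset`), the shared spikes are assigned to both trials and a warning
#' is issued.
#'
#' @param spikes a [SpikeTrainSet-class]
#' @param trials a [TrialTable-class]
#' @param alignment "onset" or "offset".
#' @param task a [TaskConfig-class]
#' @return an [EpochedSpikes-class]
#' @export
epochTrials <- function(spikes, trials, alignment = c("onset", "offset"),
                        task = TaskConfig()) {
  stopifnot(is(spikes, "SpikeTrainSet"), is(trials, "TrialTable"))
  alignment <- match.arg(alignment)
  tr <- trials@trials
  n <- nrow(tr)
  if (n == 0) .stopf("empty trial table")
  starts <- tr$onset - task@preOnset
  if (n > 1 && any(starts[-1] < tr$offset[-n]))
    .warnf("epochs overlap for %d trial pair(s); shared spikes assigned to both",
           sum(starts[-1] < tr$offset[-n]))
  ref <- if (alignment == "onset") tr$onset else tr$offset
  times <- vector("list", n)
  for (j in seq_len(n)) {
    times[[j]] <- lapply(spikes@spikes, function(st) {
      st[st >= starts[j] & st <= tr$offset[j]] - ref[j]
    })
  }
  bounds <- cbind(starts - ref, tr$offset - ref)
  new("EpochedSpikes", times = times, alignment = alignment, bounds = bounds,
      trialIds = as.integer(tr$trial_id), units = spikes@units)
}

## Gaussian kernel mass per bin for one spike, truncated at +/- 3 sigma and
## renormalised inside [wstart, wend]; returns a bins-length vector summing
## to exactly 1 for any spike inside the window.
.kernelBinMass <- function(s, edges, sigma, wstart, wend) {
  l <- max(s - 3 * sigma, wstart)
  u <- min(s + 3 * sigma, wend)
  mass <- stats::pnorm((u - s) / sigma) - stats::pnorm((l - s) / sigma)
  cut <- pmin(pmax(edges, l), u)
  diff(stats::pnorm((cut - s) / sigma)) / mass
}

#' Build a trials x units x bins firing-rate tensor
#'
#' Each spike inside the analysis window is convolved with a Gaussian kernel
#' (SD `kernelSigma`, truncated at +/- 3 SD and renormalised within the
#' window so no probability mass is lost at the edges), the smoothed mass is
#' integrated over uniform bins, and division by the bin width gives Hz.
#' The total smoothed mass per trial and unit equals the spike count inside
#' the window. With `kernelSigma = 0` spikes are counted directly into bins
#' (no smoothing); use this for the climbing slope test, whose error model
#' assumes independent bins (see [detectClimbing()]).
#'
#' @param epoched an [EpochedSpikes-class]
#' @param window `c(start, end)` in seconds relative to the alignment event;
#'   must lie inside every included trial's epoch and span an integer number
#'   of bins.
#' @param task a [TaskConfig-class] (bin width and kernel SD).
#' @return a [RateTensor-class]
#' @export
rateTensor <- function(epoched, window, task = TaskConfig()) {
  stopifnot(is(epoched, "EpochedSpikes"), length(window) == 2)
  bw <- task@binWidth
  sigma <- task@kernelSigma
  nb <- (window[2] - window[1]) / bw
  if (abs(nb - round(nb)) > 1e-9)
    .stopf("window must span an integer number of %.0f ms bins", 1000 * bw)
  nb <- as.integer(round(nb))
  if (nb < 1) .stopf("window is empty")
  bad <- which(epoched@bounds[, 1] > window[1] + 1e-9 |
                 epoched@bounds[, 2] < window[2] - 1e-9)
  if (length(bad) > 0)
    .stopf("window [%g, %g] lies outside the epoch of trial %d",
           window[1], window[2], epoched@trialIds[bad[1]])
  edges <- window[1] + bw * (0:nb)
  nt <- length(epoched@times)
  nu <- nrow(epoched@units)
  vals <- array(0, dim = c(nt, nu, nb))
  for (j in seq_len(nt)) {
    for (u in seq_len(nu)) {
      st <- epoched@times[[j]][[u]]
      st <- st[st >= window[1] & st <= window[2]]
      if (length(st) == 0) next
      if (sigma == 0) {
        idx <- pmin(findInterval(st, edges, rightmost.closed = TRUE), nb)
        vals[j, u, ] <- tabulate(idx, nbins = nb) / bw
      } else {
        acc <- numeric(nb)
        for (s in st)
          acc <- acc + .kernelBinMass(s, edges, sigma, window[1], window[2])
        vals[j, u, ] <- acc / bw
      }
    }
  }
  new("RateTensor", values = vals, binEdges = edges, binWidth = bw,
      kernelSigma = sigma, alignment = epoched@alignment,
      trialIds = epoched@trialIds, units = epoched@units)
}

#' Detect climbing (ramping) activity
#'
#' Fits an ordinary least-squares line to each unit's trial-averaged firing
#' rate as a function of bin-centre time and tests the slope against zero
#' (two-sided, alpha = 0.05). Units with a significant slope of either sign
#' are flagged as climbing. A constant trial-averaged rate yields slope 0
#' and p = 1 by convention; an exactly linear, noise-free rate with nonzero
#' slope yields p = 0.
#'
#' The OLS slope test assumes independent bin errors, so the input tensor
#' should be built without kernel smoothing (`kernelSigma = 0`): smoothing
#' spreads each spike over neighbouring bins, correlates their errors and
#' inflates the false-positive rate well above the nominal level.
#'
#' @param rates a [RateTensor-class] with at least 3 bins.
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame per unit: `unit_id`, `region`, `animal`, `slope`
#'   (Hz/s), `p`, `flagged`.
#' @export
detectClimbing <- function(rates, alpha = 0.05) {
  stopifnot(is(rates, "RateTensor"))
  nb <- dim(rates@values)[3]
  if (nb < 3) .stopf("need at least 3 bins for the slope test; got %d", nb)
  centers <- (rates@binEdges[-1] + rates@binEdges[-(nb + 1)]) / 2
  nu <- dim(rates@values)[2]
  slope <- p <- numeric(nu)
  for (u in seq_len(nu)) {
    ybar <- colMeans(rates@values[, u, , drop = FALSE])[1, ]
    if (stats::var(ybar) == 0) { slope[u] <- 0; p[u] <- 1; next }
    fit <- stats::lm(ybar ~ centers)
    ## summary.lm warns on a zero-residual (exact-line) fit; that degenerate
    ## case is resolved explicitly below
    co <- suppressWarnings(summary(fit)$coefficients)
    slope[u] <- co["centers", "Estimate"]
    pv <- co["centers", "Pr(>|t|)"]
    if (is.nan(pv))  # zero residual variance: exact line
      pv <- if (abs(slope[u]) > 0) 0 else 1
    p[u] <- pv
  }
  data.frame(unit_id = rates@units$unit_id, region = rates@units$region,
             animal = rates@units$animal, slope = slope, p = p,
             flagged = p < alpha, stringsAsFactors = FALSE)
}

#' Waveform stability rule
#'
#' A unit is kept when the mean waveform at the end of the session lies
#' sample-by-sample inside the standard-deviation band of the waveforms at
#' the beginning of the session (closed interval).
#'
#' @param pair a [WaveformPair-class]
#' @return logical: `TRUE` if stable.
#' @export
waveformStable <- function(pair) {
  stopifnot(is(pair, "WaveformPair"))
  validObject(pair)
  all(pair@endMean >= pair@startMean - pair@startSd &
        pair@endMean <= pair@startMean + pair@startSd)
}
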