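#' @include AllClasses.R constructors.R behavior.R session-io.R utils.R
NULL

## Synthetic sessions. Hold durations follow the double-Gaussian model with
## parameters interpolated across the trial index (the learning trajectory);
## spike trains are inhomogeneous Poisson processes whose within-trial rate
## follows a parametric archetype, thinned exactly against the continuous
## rate function (no binning of time).

.interpParams <- function(start, end, s) {
  DoubleGaussParams(
    gamma = (1 - s) * start@gamma + s * end@gamma,
    mu1 = (1 - s) * start@mu1 + s * end@mu1,
    sigma1 = (1 - s) * start@sigma1 + s * end@sigma1,
    mu2 = max((1 - s) * start@mu2 + s * end@mu2,
              (1 - s) * start@mu1 + s * end@mu1),
    sigma2 = (1 - s) * start@sigma2 + s * end@sigma2)
}

#' Simulate a behavioural session
#'
#' Draws each trial's hold duration from the double-Gaussian model with
#' parameters interpolated between `startParams` and `endParams` across the
#' trial index ("linear": proportional to trial index; "logistic": a sigmoid
#' centred mid-session), emulating within-session acquisition. Inter-trial
#' intervals are exponential with mean `meanIti`; the reward flag is set by
#' `duration >= criterion`. Identical seeds give identical tables.
#'
#' @param config a [BehaviorGenConfig-class]
#' @param criterion reinforcement criterion in seconds (default 1.5).
#' @return a [TrialTable-class]
#' @export
simulateBehavior <- function(config, criterion = 1.5) {
  stopifnot(is(config, "BehaviorGenConfig"))
  validObject(config)
  validObject(config@startParams)
  validObject(config@endParams)
  n <- config@nTrials
  withr::with_seed(config@seed, {
    s <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    if (config@interpolation == "logistic")
      s <- stats::plogis(10 * (s - 0.5))
    dur <- vapply(seq_len(n), function(j)
      sampleDurations(1, .interpParams(config@startParams, config@endParams,
                                       s[j])), numeric(1))
    iti <- stats::rexp(n, rate = 1 / config@meanIti)
    onset <- cumsum(iti) + c(0, cumsum(dur[-n]))
    TrialTable(trial_id = seq_len(n), onset = onset, offset = onset + dur,
               rewarded = dur >= criterion)
  })
}

#' Within-trial firing-rate profile of an archetype
#'
#' Continuous rate as a function of time from trial onset. The encoding
#' strength scales the modulation depth toward the baseline: at strength 0
#' every archetype returns exactly its baseline rate.
#'
#' * `untuned`: baseline.
#' * `time_cell`: baseline + strength * (peak - baseline) *
#'   exp(-(t - preferredTime)^2 / (2 * tuningWidth^2)).
#' * `ramp_up` / `ramp_down`: baseline + strength * slope * t.
#' * `onset_locked` / `offset_locked`: Gaussian bump (SD `tuningWidth`,
#'   height strength * (peak - baseline)) at the onset (t = 0) or at the
#'   offset (t = duration).
#'
#' Negative values are clamped to 0.
#'
#' @param archetype an [ArchetypeConfig-class]
#' @param t time from trial onset, seconds (vectorised; may be negative
#'   inside the pre-onset epoch).
#' @param strength encoding strength in \[0, 1\].
#' @param duration trial duration in seconds (required for
#'   `offset_locked`).
#' @return rate in Hz, same length as `t`.
#' @export
rateProfile <- function(archetype, t, strength, duration = NA_real_) {
  stopifnot(is(archetype, "ArchetypeConfig"))
  if (strength < 0 || strength > 1) .stopf("strength must lie in [0, 1]")
  b <- archetype@baselineRate
  amp <- strength * (archetype@peakRate - b)
  r <- switch(archetype@kind,
    untuned = rep(b, length(t)),
    time_cell = b + amp *
      exp(-(t - archetype@preferredTime)^2 / (2 * archetype@tuningWidth^2)),
    ramp_up = ,
    ramp_down = b + strength * archetype@slope * t,
    onset_locked = b + amp * exp(-t^2 / (2 * archetype@tuningWidth^2)),
    offset_locked = {
      if (!is.finite(duration))
        .stopf("offset_locked profile requires the trial duration")
      b + amp * exp(-(t - duration)^2 / (2 * archetype@tuningWidth^2))
    })
  pmax(r, 0)
}

## exact thinning of an inhomogeneous Poisson process on [t0, t1]
.thinPoisson <- function(t0, t1, rateFn, rateMax) {
  if (rateMax <= 0 || t1 <= t0) return(numeric(0))
  nCand <- stats::rpois(1, rateMax * (t1 - t0))
  if (nCand == 0) return(numeric(0))
  cand <- sort(stats::runif(nCand, t0, t1))
  keep <- stats::runif(nCand) < rateFn(cand) / rateMax
  cand[keep]
}

#' Simulate a population of spike trains for a session
#'
#' For each unit and each trial, spikes are drawn from an inhomogeneous
#' Poisson process whose rate follows the unit's archetype profile within
#' the trial epoch \[onset - preOnset, offset\]; outside trial epochs the
#' unit fires at its baseline rate. The per-stage encoding strength applies
#' the early value to the first half of trials and the late value to the
#' second half. Sampling uses exact thinning against the continuous rate
#' function and is reproducible under the config seed.
#'
#' @param trials a [TrialTable-class]
#' @param config a [PopulationGenConfig-class]
#' @param preOnset pre-onset epoch length, seconds (default 0.5).
#' @return a [SpikeTrainSet-class]
#' @export
simulatePopulation <- function(trials, config, preOnset = 0.5) {
  stopifnot(is(trials, "TrialTable"), is(config, "PopulationGenConfig"))
  validObject(config)
  tr <- trials@trials
  n <- nrow(tr)
  if (n == 0) .stopf("cannot simulate spikes for an empty trial table")
  nEarly <- ceiling(n / 2)
  kinds <- rep(seq_along(config@archetypes), config@counts)
  nu <- length(kinds)
  sessionEnd <- tr$offset[n] + 1
  ## epoch starts clipped so consecutive epochs never overlap
  epochStart <- pmax(tr$onset - preOnset, c(0, tr$offset[-n]))
  withr::with_seed(config@seed, {
    spikes <- vector("list", nu)
    for (u in seq_len(nu)) {
      arch <- config@archetypes[[kinds[u]]]
      st <- numeric(0)
      prevEnd <- 0
      for (j in seq_len(n)) {
        strength <- if (j <= nEarly) config@strengthEarly else config@strengthLate
        ## baseline segment before this trial's epoch
        st <- c(st, .thinPoisson(prevEnd, epochStart[j],
                                 function(t) rep(arch@baselineRate, length(t)),
                                 arch@baselineRate))
        ## trial epoch with the archetype profile
        dur <- tr$duration[j]
        onset <- tr$onset[j]
        probe <- c(epochStart[j] - onset, 0, arch@preferredTime, dur)
        rmax <- max(rateProfile(arch, probe, strength, duration = dur),
                    arch@baselineRate)
        st <- c(st, .thinPoisson(epochStart[j], tr$offset[j],
                                 function(t) rateProfile(arch, t - onset,
                                                         strength,
                                                         duration = dur),
                                 rmax))
        prevEnd <- tr$offset[j]
      }
      st <- c(st, .thinPoisson(prevEnd, sessionEnd,
                               function(t) rep(arch@baselineRate, length(t)),
                               arch@baselineRate))
      spikes[[u]] <- st
    }
    SpikeTrainSet(data.frame(unit_id = seq_len(nu),
                             region = config@region,
                             animal = config@animal,
                             stringsAsFactors = FALSE),
                  spikes)
  })
}

#' Simulate a multi-animal experiment to disk
#'
#' Generates one behavioural session and one or more regional populations
#' per animal, writes the session CSVs and a JSON manifest per animal/day in
#' the on-disk format read by [readSessionManifest()], and returns the
#' manifest paths. Per-animal seeds are derived deterministically from each
#' config's seed, so the whole dataset is reproducible.
#'
#' @param animals list of per-animal specs, each a list with elements
#'   `id` (unique label), `behavior` ([BehaviorGenConfig-class]) and
#'   `populations` (list of [PopulationGenConfig-class]; their `animal`
#'   field is overwritten with `id`).
#' @param outDir output directory (created if needed).
#' @param day session day label (default 1).
#' @param task a [TaskConfig-class]
#' @return character vector of manifest paths, named by animal id.
#' @export
simulateExperiment <- function(animals, outDir, day = 1, task = TaskConfig()) {
  ids <- vapply(animals, function(a) as.character(a$id), character(1))
  if (anyDuplicated(ids) > 0)
    .stopf("duplicate animal id '%s'", ids[anyDuplicated(ids)])
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifests <- character(length(animals))
  for (k in seq_along(animals)) {
    a <- animals[[k]]
    trials <- simulateBehavior(a$behavior, criterion = task@criterion)
    allSpikes <- NULL
    for (pop in a$populations) {
      pop@animal <- ids[k]
      sts <- simulatePopulation(trials, pop, preOnset = task@preOnset)
      if (is.null(allSpikes)) {
        allSpikes <- sts
      } else {
        off <- max(allSpikes@units$unit_id)
        u <- sts@units
        u$unit_id <- u$unit_id + off
        allSpikes <- SpikeTrainSet(rbind(allSpikes@units, u),
                                   c(allSpikes@spikes, sts@spikes))
      }
    }
    base <- sprintf("%s_day%d", ids[k], as.integer(day))
    writeTrials(trials, file.path(outDir, paste0(base, "_trials.csv")))
    writeSpikes(allSpikes, file.path(outDir, paste0(base, "_spikes.csv")))
    manifests[k] <- file.path(outDir, paste0(base, "_manifest.json"))
    writeSessionManifest(manifests[k], animal = ids[k], day = day,
                         trialsFile = paste0(base, "_trials.csv"),
                         spikesFile = paste0(base, "_spikes.csv"),
                         task = task)
  }
  names(manifests) <- ids
  manifests
}
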